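# Day-subsampling reliability analysis: how well do cumulative load
# estimates from k of the first six recorded days (k = 1..6) agree with the
# full-dataset estimates? Agreement is described by the mean absolute
# percent error (MAPE), the Pearson correlation of subset-mean estimates
# against the reference across participants, and the intraclass correlation
# ICC(2,1) across same-size subsets.

#' Enumerate day subsets of a given size
#'
#' All `choose(6, k)` combinations of the participant's first six recorded
#' days, in lexicographic (day-ordered) order: for `k = 5` these are the six
#' leave-one-day-out subsets, for `k = 1` the six single days.
#'
#' @param recorded_days Integer vector of recorded day indices, in recording
#'   order; at least six are required.
#' @param k Days per subset, 1..6.
#' @return A list of integer vectors, each a day-index combination.
#' @export
#' @examples
#' length(enumerate_subsets(1:8, 3)) # choose(6, 3) = 20
enumerate_subsets <- function(recorded_days, k) {
  if (length(recorded_days) < 6L) {
    stop_tendonload("participant has fewer than 6 recorded days",
                    "domain")
  }
  if (k < 1 || k > 6) {
    stop_tendonload("subset size k must lie in 1..6", "domain")
  }
  first6 <- recorded_days[1:6]
  combs <- combn(first6, k)
  lapply(seq_len(ncol(combs)), function(j) combs[, j])
}

#' Mean absolute percent error against a reference
#'
#' `mean(|estimate - reference| / reference) * 100` over all
#' (participant, subset) pairs. Participants whose reference is zero are
#' dropped with a warning (the percent error is undefined).
#'
#' @param estimates Tibble with columns `participant_id` and `estimate`
#'   (one row per participant x subset).
#' @param reference Tibble with columns `participant_id` and `reference`
#'   (one row per participant).
#' @return MAPE in percent.
#' @export
mape <- function(estimates, reference) {
  errs <- abs_pct_errors(estimates, reference)
  mean(errs$pct_error)
}

abs_pct_errors <- function(estimates, reference) {
  zero <- reference$participant_id[reference$reference == 0]
  if (length(zero) > 0L) {
    warn(paste0("dropping participant(s) with zero reference from MAPE: ",
                paste(zero, collapse = ", ")))
    reference <- dplyr::filter(reference, .data$reference != 0)
  }
  dplyr::inner_join(estimates, reference, by = "participant_id") |>
    dplyr::mutate(
      pct_error = abs(.data$estimate - .data$reference) /
        .data$reference * 100)
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' Thin wrapper over [stats::cor.test()] (t transform, n - 2 df). With
#' fewer than three pairs or zero variance in either vector the correlation
#' is undefined and returned as `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with elements `r`, `p` and `n`.
#' @export
pearson <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L || sd(x) == 0 || sd(y) == 0) {
    warn("Pearson correlation undefined (n < 3 or zero variance)")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures, from the
#' standard mean-squares decomposition of the participants x measurements
#' matrix:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with `MSR`, `MSC`, `MSE` the row (participant), column (measurement) and
#' residual mean squares. Rows with missing cells are dropped complete-case
#' with a warning.
#'
#' @param mat Numeric matrix, participants in rows, repeated measurements
#'   (e.g. same-size day subsets, day-ordered) in columns.
#' @return The ICC(2,1) estimate.
#' @export
#' @examples
#' m <- cbind(1:5, 1:5 + 0.1, 1:5 - 0.1)
#' icc(m)
icc <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) {
    warn("dropping rows with missing cells for ICC")
    mat <- mat[complete.cases(mat), , drop = FALSE]
  }
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2L || k < 2L) {
    stop_tendonload("ICC needs at least 2 rows and 2 columns", "domain")
  }
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

subset_estimates <- function(daily, participants, k) {
  # per participant: day-ordered first-6 subsets of size k; per subset the
  # summed raw metrics and the derived per-hour norms
  purrr::map(participants, function(pid) {
    pd <- dplyr::filter(daily, .data$participant_id == pid)
    days <- pd$day_index
    subsets <- enumerate_subsets(days, k)
    purrr::imap(subsets, function(dd, j) {
      sel <- pd[pd$day_index %in% dd, ]
      lt <- sum(sel$loading_time_h)
      tibble::tibble(
        participant_id = pid,
        subset = j,
        k = k,
        loading_time_h = lt,
        high_time_h = sum(sel$high_time_h),
        overall_impulse_bwh = sum(sel$overall_impulse_bwh),
        high_impulse_bwh = sum(sel$high_impulse_bwh),
        norm_overall = ifelse(lt > 0, sum(sel$overall_impulse_bwh) / lt,
                              NA_real_),
        norm_high = ifelse(lt > 0, sum(sel$high_impulse_bwh) / lt,
                           NA_real_)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Day-subsampling reliability analysis
#'
#' For each subset size `k` in 1..6 and each normalized metric
#' (`norm_overall`, `norm_high`): computes the absolute percent errors of
#' all day-ordered subsets of the first six recorded days against the
#' full-dataset (all recorded days) reference, their mean and SD, the
#' Pearson correlation of per-participant subset means against the
#' reference, and the ICC(2,1) across subsets. Participants with fewer than
#' six recorded days are excluded with a warning.
#'
#' @param daily Per-day metric table from [daily_load_metrics()], covering
#'   all participants (rows ordered by recording day within participant).
#' @param k Integer vector of subset sizes to evaluate (subset of 1..6).
#' @return A tibble of class `reliability_report`: `metric`, `k`,
#'   `mape_mean`, `mape_sd`, `pearson_r`, `icc`, `n_subsets`,
#'   `n_participants`.
#' @export
reliability_analysis <- function(daily, k = 1:6) {
  counts <- dplyr::count(daily, .data$participant_id)
  short <- counts$participant_id[counts$n < 6L]
  if (length(short) > 0L) {
    warn(paste0("excluding participant(s) with fewer than 6 recorded days: ",
                paste(short, collapse = ", ")))
    daily <- dplyr::filter(daily,
                           !.data$participant_id %in% short)
  }
  participants <- sort(unique(daily$participant_id))
  if (length(participants) < 2L) {
    stop_tendonload("reliability analysis needs at least 2 participants",
                    "domain")
  }
  reference <- daily |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      loading_time_h = sum(.data$loading_time_h),
      overall_impulse_bwh = sum(.data$overall_impulse_bwh),
      high_impulse_bwh = sum(.data$high_impulse_bwh),
      .groups = "drop") |>
    dplyr::mutate(
      norm_overall = .data$overall_impulse_bwh / .data$loading_time_h,
      norm_high = .data$high_impulse_bwh / .data$loading_time_h)

  metrics <- c("norm_overall", "norm_high")
  rows <- purrr::map(k, function(kk) {
    est <- subset_estimates(daily, participants, kk)
    purrr::map(metrics, function(m) {
      ref_m <- tibble::tibble(participant_id = reference$participant_id,
                              reference = reference[[m]])
      est_m <- tibble::tibble(participant_id = est$participant_id,
                              subset = est$subset,
                              estimate = est[[m]])
      errs <- abs_pct_errors(est_m, ref_m)
      subj_mean <- est_m |>
        dplyr::group_by(.data$participant_id) |>
        dplyr::summarise(estimate = mean(.data$estimate), .groups = "drop") |>
        dplyr::inner_join(ref_m, by = "participant_id")
      pr <- pearson(subj_mean$estimate, subj_mean$reference)
      n_sub <- max(est_m$subset)
      icc_val <- if (n_sub >= 2L) {
        wide <- tidyr::pivot_wider(est_m, names_from = "subset",
                                   values_from = "estimate")
        icc(as.matrix(wide[, -1]))
      } else {
        NA_real_
      }
      tibble::tibble(
        metric = sub("norm_", "", m),
        k = kk,
        mape_mean = mean(errs$pct_error),
        mape_sd = sd(errs$pct_error),
        pearson_r = pr$r,
        icc = icc_val,
        n_subsets = n_sub,
        n_participants = length(participants)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  class(rows) <- c("reliability_report", class(rows))
  rows
}

#' @export
tidy.reliability_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.reliability_report <- function(x, ...) {
  x |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mape_k1 = .data$mape_mean[.data$k == min(.data$k)],
      mape_kmax = .data$mape_mean[.data$k == max(.data$k)],
      icc_k1 = .data$icc[.data$k == min(.data$k)],
      n_participants = .data$n_participants[[1L]],
      .groups = "drop")
}

#' Plot a reliability report
#'
#' Mean absolute percent error (with +/- 1 SD bars), Pearson correlation or
#' ICC as a function of the number of days used, by metric.
#'
#' @param object A `reliability_report`.
#' @param what One of `"mape"`, `"pearson"`, `"icc"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.reliability_report <- function(object,
                                        what = c("mape", "pearson", "icc"),
                                        ...) {
  what <- match.arg(what)
  df <- tibble::as_tibble(object)
  p <- switch(what,
    mape = ggplot(df, aes(x = .data$k, y = .data$mape_mean,
                          colour = .data$metric)) +
      geom_errorbar(aes(ymin = pmax(0, .data$mape_mean - .data$mape_sd),
                        ymax = .data$mape_mean + .data$mape_sd),
                    width = 0.15) +
      geom_line() + geom_point() +
      labs(y = "mean absolute percent error (%)"),
    pearson = ggplot(df, aes(x = .data$k, y = .data$pearson_r,
                             colour = .data$metric)) +
      geom_line() + geom_point() + labs(y = "Pearson r vs. full dataset"),
    icc = ggplot(df, aes(x = .data$k, y = .data$icc,
                         colour = .data$metric)) +
      geom_line() + geom_point() + labs(y = "ICC(2,1)"))
  p + labs(x = "days of insole data used") +
    scale_colour_brewer(palette = "Set1") +
    theme_minimal()
}
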