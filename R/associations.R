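# Associations between the normalized cumulative load biomarkers and
# clinical / functional measures: Pearson correlation rows with an a-priori
# strength classification (|r| >= 0.6 strong, 0.4-0.6 moderate, < 0.4
# weak), significance at alpha = 0.05 kept only as an ancillary flag, and
# normalization utilities for dynamometer and jump measures.

#' Classify Pearson correlation strength
#'
#' `strong` iff `|r| >= 0.6`; `moderate` iff `0.4 <= |r| < 0.6`; `weak` iff
#' `|r| < 0.4`. Boundaries are closed from below (0.4 is moderate, 0.6 is
#' strong). Vectorized; the three categories partition `[-1, 1]`.
#'
#' @param r Correlation value(s), `|r| <= 1` (NA allowed).
#' @return A character vector in `{"weak", "moderate", "strong"}`.
#' @export
#' @examples
#' classify_strength(c(0.625, 0.543, 0.392, -0.62))
classify_strength <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop_tendonload("|r| must not exceed 1", "domain")
  }
  out <- rep(NA_character_, length(r))
  a <- abs(r)
  out[a < 0.4] <- "weak"
  out[a >= 0.4 & a < 0.6] <- "moderate"
  out[a >= 0.6] <- "strong"
  out
}

#' Correlation table of load biomarkers against outcome measures
#'
#' One row per (load measure x outcome measure) pair: complete-pair count,
#' Pearson r, two-sided p (t transform, n - 2 df), strength class and
#' significance flag at `alpha`. No multiple-testing correction is applied;
#' significance is ancillary to the descriptive strength class. Pairs with
#' fewer than three complete observations or zero variance are flagged in
#' the `note` column rather than dropped.
#'
#' @param loads Tibble with `participant_id` and the load measure columns.
#' @param outcomes Tibble with `participant_id` and outcome columns
#'   (functional measures, survey scores, age, ...).
#' @param load_measures Character; load columns to correlate.
#' @param outcome_measures Character; outcome columns to correlate
#'   (default: every non-id numeric column of `outcomes`).
#' @param alpha Significance level for the ancillary flag.
#' @return A tibble of class `correlation_table` with columns `x_name`,
#'   `y_name`, `n`, `r`, `p`, `strength`, `significant`, `note`.
#' @export
correlation_table <- function(loads, outcomes,
                              load_measures = c("norm_overall_bw",
                                                "norm_high_bw"),
                              outcome_measures = NULL,
                              alpha = 0.05) {
  if (is.null(outcome_measures)) {
    outcome_measures <- setdiff(
      names(outcomes)[vapply(outcomes, is.numeric, TRUE)],
      "participant_id")
  }
  joined <- dplyr::inner_join(loads, outcomes, by = "participant_id")
  grid <- tidyr::expand_grid(x_name = load_measures,
                             y_name = outcome_measures)
  rows <- purrr::pmap(grid, function(x_name, y_name) {
    x <- joined[[x_name]]
    y <- joined[[y_name]]
    keep <- complete.cases(x, y)
    n <- sum(keep)
    if (n < 3L) {
      return(tibble::tibble(x_name = x_name, y_name = y_name, n = n,
                            r = NA_real_, p = NA_real_,
                            strength = NA_character_, significant = NA,
                            note = "insufficient pairs"))
    }
    if (sd(x[keep]) == 0 || sd(y[keep]) == 0) {
      return(tibble::tibble(x_name = x_name, y_name = y_name, n = n,
                            r = NA_real_, p = NA_real_,
                            strength = NA_character_, significant = NA,
                            note = "zero variance"))
    }
    pr <- pearson(x[keep], y[keep])
    tibble::tibble(x_name = x_name, y_name = y_name, n = n,
                   r = pr$r, p = pr$p,
                   strength = classify_strength(pr$r),
                   significant = pr$p < alpha,
                   note = "")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("correlation_table", class(out))
  out
}

#' @export
tidy.correlation_table <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.correlation_table <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_strong = sum(x$strength == "strong", na.rm = TRUE),
    n_moderate = sum(x$strength == "moderate", na.rm = TRUE),
    n_weak = sum(x$strength == "weak", na.rm = TRUE),
    n_significant = sum(x$significant, na.rm = TRUE)
  )
}

#' Plot a correlation table
#'
#' Dot plot of r by outcome measure, faceted by load measure and coloured
#' by strength class.
#'
#' @param object A `correlation_table`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.correlation_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df, aes(x = .data$r, y = .data$y_name,
                 colour = .data$strength)) +
    geom_point(size = 2) +
    geom_hline(yintercept = 0, colour = NA) +
    facet_wrap(~ .data$x_name) +
    scale_colour_brewer(palette = "Dark2", na.value = "grey70") +
    labs(x = "Pearson r", y = NULL) +
    theme_minimal()
}

#' Normalized plantar flexor capacity measures from a torque trace
#'
#' Reduces a dynamometer torque-time trace (with plantarflexion angular
#' velocity) to the three normalized capacity scalars: peak moment
#' (`%H*W`, i.e. torque / (height x weight) x 100), peak power
#' (`%H*W*rad/s`, from torque x angular velocity) and mechanical work per
#' contraction (`%H*W*rad`, the time integral of power). When a `rep`
#' column is present the measures are averaged across repetitions.
#'
#' @param trace Data frame with columns `t_s` (s), `torque_nm` (N m),
#'   `omega_rad_s` (rad/s) and optionally `rep`.
#' @param height Body height in m (> 0).
#' @param weight Body weight in N (> 0).
#' @return A one-row tibble: `peak_moment`, `peak_power`, `work` (percent
#'   units as above).
#' @export
#' @examples
#' tr <- data.frame(t_s = seq(0, 1, 0.01), torque_nm = 100,
#'                  omega_rad_s = 0.5)
#' capacity_measures(tr, height = 2, weight = 500)
capacity_measures <- function(trace, height, weight) {
  if (!is.finite(height) || height <= 0 || !is.finite(weight) ||
      weight <= 0) {
    stop_tendonload("height and weight must be > 0", "domain")
  }
  if (!all(is.finite(trace$torque_nm))) {
    stop_tendonload("torque trace must be finite", "domain")
  }
  hw <- height * weight
  reps <- if ("rep" %in% names(trace)) {
    split(trace, trace$rep)
  } else {
    list(trace)
  }
  per_rep <- purrr::map(reps, function(d) {
    power <- d$torque_nm * d$omega_rad_s
    tibble::tibble(
      peak_moment = max(d$torque_nm) / hw * 100,
      peak_power = max(power) / hw * 100,
      work = pracma::trapz(d$t_s, power) / hw * 100
    )
  })
  dplyr::bind_rows(per_rep) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean))
}

#' Normalize a height measure to percent body height
#'
#' @param measure_m Measured height (heel raise or jump) in m.
#' @param height Body height in m (> 0).
#' @return Value in %BH.
#' @export
#' @examples
#' normalize_height(0.10, 1.72)
normalize_height <- function(measure_m, height) {
  if (!is.finite(height) || height <= 0) {
    stop_tendonload("height must be > 0", "domain")
  }
  measure_m / height * 100
}
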