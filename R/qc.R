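# Quality control: unloaded-epoch detection, piecewise-constant baseline
# drift correction, and screening of erroneous sessions before any load is
# estimated. Contact force from an unworn or unloaded insole should read
# zero; a quiet epoch whose level sits away from zero is a nonphysical
# offset and is removed here.

#' QC rule set
#'
#' Tunable thresholds for unloaded-epoch detection, drift correction and
#' session screening. Defaults are this package's choices (the underlying
#' screening criteria in field studies are applied numerically and
#' graphically and are not standardized): 10-s epochs, a 20 N quiet range,
#' sessions flagged when less than 2% of epochs are ever unloaded over >10
#' minutes, a 10xBW plausibility ceiling on 1-s mean force, and a 5 N noise
#' floor for negative-force screening.
#'
#' @param epoch_s Epoch length in seconds for unloaded detection.
#' @param quiet_threshold_n An epoch is unloaded iff the within-epoch range
#'   of total force is below this value (Newtons). A range criterion is used
#'   (not a level criterion) so that a quiet epoch sitting on a constant
#'   offset is still recognised as unloaded.
#' @param min_unloaded_fraction Sessions whose unloaded-epoch fraction falls
#'   below this, with duration above `min_duration_s`, are excluded as
#'   initialization failures (never-unloaded signature).
#' @param min_duration_s Minimum duration for the never-unloaded rule.
#' @param max_bw_multiple Exclusion ceiling on any 1-s mean of total force,
#'   as a multiple of body weight.
#' @param noise_floor_n Negative forces beyond this magnitude (before
#'   clipping) count toward the negative-dominance rule.
#' @return A list of class `qc_rules`.
#' @export
qc_rules <- function(epoch_s = 10, quiet_threshold_n = 20,
                     min_unloaded_fraction = 0.02, min_duration_s = 600,
                     max_bw_multiple = 10, noise_floor_n = 5) {
  if (epoch_s <= 0 || quiet_threshold_n < 0) {
    stop_tendonload("epoch_s must be > 0 and quiet_threshold_n >= 0",
                    "domain")
  }
  structure(
    list(epoch_s = epoch_s, quiet_threshold_n = quiet_threshold_n,
         min_unloaded_fraction = min_unloaded_fraction,
         min_duration_s = min_duration_s,
         max_bw_multiple = max_bw_multiple,
         noise_floor_n = noise_floor_n),
    class = "qc_rules")
}

epoch_ids <- function(n, sample_rate, epoch_s) {
  len <- max(1L, round(epoch_s * sample_rate))
  n_ep <- max(1L, n %/% len)
  # a trailing partial epoch is merged into the last full epoch
  pmin(((seq_len(n) - 1L) %/% len) + 1L, n_ep)
}

# lower median: always one of the sample values, so that subtracting it and
# clipping at zero leaves an epoch whose lower median is exactly zero --
# this makes drift correction idempotent to machine precision
median_low <- function(x) sort(x)[(length(x) + 1L) %/% 2L]

#' Detect unloaded epochs of a recording
#'
#' Splits the session into non-overlapping epochs and marks an epoch
#' unloaded iff the within-epoch range of total force (sum of the three
#' channels) is below `quiet_threshold_n`. The range criterion makes the
#' detector insensitive to constant offsets: a sensor left reading a steady
#' 800 N while unworn is still quiet.
#'
#' @param rec An [insole_recording()].
#' @param rules A [qc_rules()] object supplying `epoch_s` and
#'   `quiet_threshold_n`.
#' @return A tibble with one row per epoch: `epoch`, `i_start`, `i_end`,
#'   `t_start`, `t_end`, `unloaded`.
#' @export
detect_unloaded_epochs <- function(rec, rules = qc_rules()) {
  fs <- sample_rate(rec)
  n <- nrow(rec)
  if (n < rules$epoch_s * fs) {
    warn("recording shorter than one epoch; treating it as a single epoch")
  }
  ids <- epoch_ids(n, fs, rules$epoch_s)
  total <- total_force(rec)
  rng <- vapply(split(total, ids), function(x) max(x) - min(x), 0)
  idx <- split(seq_len(n), ids)
  i_start <- vapply(idx, `[[`, 0L, 1L)
  i_end <- vapply(idx, function(i) i[[length(i)]], 0L)
  tibble::tibble(
    epoch = seq_along(rng),
    i_start = i_start,
    i_end = i_end,
    t_start = rec$t[i_start],
    t_end = rec$t[i_end],
    unloaded = unname(rng) < rules$quiet_threshold_n
  )
}

fill_constant <- function(x) {
  # forward-fill, then back-fill the leading run of NAs
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  first <- which(ok)[1L]
  idx[idx == 0L] <- first
  x[idx]
}

#' Correct nonphysical baseline drift
#'
#' For each channel, takes the (lower) median level within every unloaded
#' epoch as a baseline anchor, holds it piecewise-constant between unloaded
#' epochs
#' (carry-forward, with the first anchor carried backward), subtracts it,
#' and clips the corrected force at 0 N from below (contact force is
#' non-negative). After correction the median total force in every unloaded
#' epoch is 0 within 1e-6 N. If no unloaded epoch exists nothing is
#' changed and the status is `pass` with a warning.
#'
#' @param rec An [insole_recording()].
#' @param epochs Epoch table from [detect_unloaded_epochs()]; computed if
#'   missing.
#' @param rules A [qc_rules()]; `noise_floor_n` is used to tally negative
#'   samples before clipping for downstream screening.
#' @return A list with `recording` (corrected), and `report` -- a one-row
#'   tibble with `session_id`, `status` (`pass`/`corrected`),
#'   `fraction_unloaded`, `max_abs_offset_n`, `neg_fraction` (fraction of
#'   samples with any channel below `-noise_floor_n` before clipping) and a
#'   list-column `offsets` of per-epoch anchor levels.
#' @export
correct_baseline_drift <- function(rec, epochs = NULL, rules = qc_rules()) {
  if (is.null(epochs)) epochs <- detect_unloaded_epochs(rec, rules)
  ids <- epoch_ids(nrow(rec), sample_rate(rec), rules$epoch_s)
  unloaded <- epochs$unloaded
  channels <- c("f_heel", "f_mid", "f_fore")

  if (!any(unloaded)) {
    warn("no unloaded epoch found; baseline drift not corrected")
    report <- tibble::tibble(
      session_id = attr(rec, "session_id"),
      status = "pass",
      fraction_unloaded = 0,
      max_abs_offset_n = 0,
      neg_fraction = neg_fraction(rec, rules$noise_floor_n),
      offsets = list(tibble::tibble())
    )
    return(list(recording = rec, report = report))
  }

  anchor_tbl <- epochs[, c("epoch", "t_start", "t_end", "unloaded")]
  corrected <- rec
  neg <- rep(FALSE, nrow(rec))
  max_offset <- 0
  for (ch in channels) {
    anchors <- rep(NA_real_, nrow(epochs))
    med <- vapply(split(rec[[ch]], ids)[unloaded], median_low, 0)
    anchors[unloaded] <- med
    offset_by_epoch <- fill_constant(anchors)
    offset <- offset_by_epoch[ids]
    raw <- rec[[ch]] - offset
    neg <- neg | (raw < -rules$noise_floor_n)
    corrected[[ch]] <- pmax(0, raw)
    anchor_tbl[[ch]] <- offset_by_epoch
    max_offset <- max(max_offset, max(abs(anchors), na.rm = TRUE))
  }
  status <- if (max_offset > 1e-6) "corrected" else "pass"
  report <- tibble::tibble(
    session_id = attr(rec, "session_id"),
    status = status,
    fraction_unloaded = mean(unloaded),
    max_abs_offset_n = max_offset,
    neg_fraction = mean(neg),
    offsets = list(anchor_tbl)
  )
  list(recording = corrected, report = report)
}

neg_fraction <- function(rec, noise_floor_n) {
  mean(rec$f_heel < -noise_floor_n | rec$f_mid < -noise_floor_n |
         rec$f_fore < -noise_floor_n)
}

#' Screen a drift-corrected recording for exclusion
#'
#' Applies the session-level exclusion rules and always returns a report.
#' A session is excluded when any of the following fires:
#' \describe{
#'   \item{never-unloaded}{the unloaded-epoch fraction is below
#'     `min_unloaded_fraction` and the session is longer than
#'     `min_duration_s` -- the signature of an incorrectly initialized
#'     sensor that never reads a quiet baseline;}
#'   \item{implausible-magnitude}{any 1-s mean of total force exceeds
#'     `max_bw_multiple` times body weight;}
#'   \item{negative-dominance}{more than 1% of samples fell below
#'     `-noise_floor_n` before clipping (taken from the drift report).}
#' }
#'
#' @param rec A drift-corrected [insole_recording()].
#' @param profile The wearer's [participant_profile()] (for body weight).
#' @param rules A [qc_rules()].
#' @param drift_report Optional report from [correct_baseline_drift()];
#'   supplies `neg_fraction` and the corrected status.
#' @return A one-row tibble: `participant_id`, `session_id`, `day_index`,
#'   `status` (`pass`/`corrected`/`excluded`), `exclusion_reason`,
#'   `fraction_unloaded`, `duration_h`.
#' @export
screen_recording <- function(rec, profile, rules = qc_rules(),
                             drift_report = NULL) {
  fs <- sample_rate(rec)
  epochs <- detect_unloaded_epochs(rec, rules)
  frac_unloaded <- mean(epochs$unloaded)
  duration_s <- nrow(rec) / fs
  total <- total_force(rec)

  reasons <- character()
  if (frac_unloaded < rules$min_unloaded_fraction &&
      duration_s > rules$min_duration_s) {
    reasons <- c(reasons, "never-unloaded")
  }
  win <- max(1L, round(fs))
  n_win <- floor(length(total) / win)
  if (n_win >= 1L) {
    means <- colMeans(matrix(total[seq_len(n_win * win)], nrow = win))
    if (any(means > rules$max_bw_multiple * profile$body_weight)) {
      reasons <- c(reasons, "implausible-magnitude")
    }
  }
  negf <- if (!is.null(drift_report)) drift_report$neg_fraction else 0
  if (negf > 0.01) {
    reasons <- c(reasons, "negative-dominance")
  }

  excluded <- length(reasons) > 0L
  status <- if (excluded) {
    "excluded"
  } else if (!is.null(drift_report)) {
    drift_report$status
  } else {
    "pass"
  }
  tibble::tibble(
    participant_id = attr(rec, "participant_id"),
    session_id = attr(rec, "session_id"),
    day_index = attr(rec, "day_index"),
    status = status,
    exclusion_reason = if (excluded) paste(reasons, collapse = ";") else "",
    fraction_unloaded = frac_unloaded,
    duration_h = duration_s / 3600
  )
}

#' Run drift correction and screening on one session
#'
#' Convenience wrapper chaining [detect_unloaded_epochs()],
#' [correct_baseline_drift()] and [screen_recording()].
#'
#' @inheritParams screen_recording
#' @return A list with `recording` (corrected) and `report` (screening
#'   report row, including `neg_fraction` and `max_abs_offset_n` from the
#'   drift stage).
#' @export
qc_session <- function(rec, profile, rules = qc_rules()) {
  epochs <- detect_unloaded_epochs(rec, rules)
  drift <- if (any(epochs$unloaded)) {
    correct_baseline_drift(rec, epochs, rules)
  } else {
    # avoid duplicating the warning path: build a pass report directly
    list(recording = rec, report = tibble::tibble(
      session_id = attr(rec, "session_id"), status = "pass",
      fraction_unloaded = 0, max_abs_offset_n = 0,
      neg_fraction = neg_fraction(rec, rules$noise_floor_n),
      offsets = list(tibble::tibble())))
  }
  screen <- screen_recording(drift$recording, profile, rules,
                             drift_report = drift$report)
  screen$neg_fraction <- drift$report$neg_fraction
  screen$max_abs_offset_n <- drift$report$max_abs_offset_n
  list(recording = drift$recording, report = screen)
}
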