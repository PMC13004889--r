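# Cumulative tendon load biomarkers. Two magnitude thresholds stratify the
# load trace: 0.3xBW (the load of the lowest-loading tendon exercise,
# seated heel raises) delimits "overall" loading and defines total loading
# time; 3.0xBW (approximately the peak tendon load of walking) delimits
# "high-level" loading incurred by dynamic activity. Cumulative impulse
# above a threshold integrates the full load magnitude (area down to zero)
# over supra-threshold samples; per-hour values divide by the overall
# loading time.

default_thresholds <- function() c(overall = 0.3, high = 3.0)

#' Time spent at or above a load threshold
#'
#' Counts samples with `load >= thr` and converts to hours at the trace's
#' sample rate. The indicator is samplewise; threshold crossings are
#' resolved at sample resolution with no sub-sample interpolation.
#'
#' @param trace A `tendon_load_trace` from [estimate_trace()].
#' @param thr Threshold in xBW (>= 0).
#' @return Hours at or above `thr`.
#' @export
#' @examples
#' # 2 h at a constant 1 xBW
#' tr <- tendonload:::new_tendon_load_trace(
#'   t = seq(0, 7200 - 0.05, by = 0.05), load = rep(1, 144000),
#'   meta = list(participant_id = "P", session_id = "S",
#'               start_time = Sys.time(), sample_rate = 20, day_index = 1L))
#' time_above(tr, 0.3)
time_above <- function(trace, thr) {
  if (thr < 0) stop_tendonload("threshold must be >= 0", "domain")
  if (nrow(trace) == 0L) return(0)
  sum(trace$load >= thr) / sample_rate(trace) / 3600
}

#' Cumulative load impulse at or above a threshold
#'
#' Trapezoidal integral of the full load magnitude over supra-threshold
#' samples: the load is masked to 0 where it falls below `thr` and the
#' masked trace is integrated down to zero (not just the excess above the
#' threshold line). Units are xBW x hour.
#'
#' @inheritParams time_above
#' @return Impulse in xBW x hour.
#' @export
impulse_above <- function(trace, thr) {
  if (thr < 0) stop_tendonload("threshold must be >= 0", "domain")
  if (nrow(trace) < 2L) return(0)
  masked <- ifelse(trace$load >= thr, trace$load, 0)
  pracma::trapz(trace$t, masked) / 3600
}

trace_day <- function(trace) attr(trace, "day_index")

#' Per-day raw loading metrics for a set of traces
#'
#' Sums [time_above()] and [impulse_above()] at both thresholds across the
#' sessions of each day. Sessions are treated independently (inter-session
#' gaps contribute nothing); raw times and impulses are additive across
#' sessions and days.
#'
#' @param traces A list of `tendon_load_trace` objects from one participant.
#' @param thresholds Named numeric `c(overall =, high =)` in xBW.
#' @return A tibble with one row per day: `participant_id`, `day_index`,
#'   `loading_time_h`, `high_time_h`, `overall_impulse_bwh`,
#'   `high_impulse_bwh`.
#' @export
daily_load_metrics <- function(traces, thresholds = default_thresholds()) {
  if (inherits(traces, "tendon_load_trace")) traces <- list(traces)
  rows <- purrr::map(traces, function(tr) {
    tibble::tibble(
      participant_id = attr(tr, "participant_id"),
      day_index = trace_day(tr),
      loading_time_h = time_above(tr, thresholds[["overall"]]),
      high_time_h = time_above(tr, thresholds[["high"]]),
      overall_impulse_bwh = impulse_above(tr, thresholds[["overall"]]),
      high_impulse_bwh = impulse_above(tr, thresholds[["high"]])
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$participant_id, .data$day_index) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum),
                     .groups = "drop") |>
    dplyr::arrange(.data$participant_id, .data$day_index)
}

#' Cumulative load summary over a set of days
#'
#' Sums loading time and impulse at the overall (0.3xBW) and high (3.0xBW)
#' thresholds over the selected days, then normalizes both impulses by the
#' overall loading time -- the denominator for the high-level per-hour value
#' is also the overall loading time, not the (much shorter) high-level time,
#' so the normalized high-level load reads as high-level impulse accumulated
#' per hour of any loading. When the loading time is zero the normalized
#' values are undefined and returned as `NA` with a warning.
#'
#' @param x Either a list of `tendon_load_trace` objects or a per-day metric
#'   table from [daily_load_metrics()].
#' @param days Optional integer vector restricting to a subset of
#'   `day_index` values; default uses all days present.
#' @param thresholds Named numeric `c(overall =, high =)` in xBW (only used
#'   when `x` is a list of traces).
#' @return A one-row tibble of class `cumulative_load_summary`:
#'   `participant_id`, `days_included` (list-column), `wear_days`,
#'   `loading_time_h`, `high_time_h`, `overall_impulse_bwh`,
#'   `high_impulse_bwh`, `norm_overall_bw`, `norm_high_bw`, `thr_overall`,
#'   `thr_high`.
#' @export
summarize_load <- function(x, days = NULL,
                           thresholds = default_thresholds()) {
  daily <- if (is.data.frame(x)) x else daily_load_metrics(x, thresholds)
  if (!is.null(days)) {
    daily <- dplyr::filter(daily, .data$day_index %in% days)
  }
  pid <- if (nrow(daily) > 0L) daily$participant_id[[1L]] else NA_character_
  loading_time <- sum(daily$loading_time_h)
  high_time <- sum(daily$high_time_h)
  overall_imp <- sum(daily$overall_impulse_bwh)
  high_imp <- sum(daily$high_impulse_bwh)
  if (loading_time > 0) {
    norm_overall <- overall_imp / loading_time
    norm_high <- high_imp / loading_time
  } else {
    warn("loading time is zero; normalized per-hour loads are undefined")
    norm_overall <- NA_real_
    norm_high <- NA_real_
  }
  out <- tibble::tibble(
    participant_id = pid,
    days_included = list(sort(unique(daily$day_index))),
    wear_days = length(unique(daily$day_index)),
    loading_time_h = loading_time,
    high_time_h = high_time,
    overall_impulse_bwh = overall_imp,
    high_impulse_bwh = high_imp,
    norm_overall_bw = norm_overall,
    norm_high_bw = norm_high,
    thr_overall = thresholds[["overall"]],
    thr_high = thresholds[["high"]]
  )
  class(out) <- c("cumulative_load_summary", class(out))
  out
}
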