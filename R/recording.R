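# On-disk data model and containers for insole recordings.
#
# A recording is a tibble of per-sample forces plus session metadata kept in
# attributes; the project dialect on disk is a CSV of samples
# (time_s, f_heel_n, f_mid_n, f_fore_n) with a JSON sidecar holding the
# metadata (participant_id, session_id, start_time, sample_rate, day_index).

#' Construct an insole recording
#'
#' Builds a validated single-session recording of the three plantar force
#' channels (heel, midfoot, forefoot) logged by an instrumented insole.
#' Timestamps are regular at `1 / sample_rate`; if `t` is supplied it is
#' checked for strict monotonicity and a uniform step, then regularized onto
#' the nominal grid.
#'
#' @param f_heel,f_mid,f_fore Numeric vectors of equal length; per-sample
#'   contact force in Newtons under the heel, midfoot and forefoot pads.
#' @param participant_id,session_id Character scalars identifying the wearer
#'   and the recording session.
#' @param start_time `POSIXct` scalar; wall-clock start of the session.
#' @param sample_rate Sampling rate in Hz (nominal 20).
#' @param day_index 1-based calendar day within the monitoring period, or
#'   `NA` until assigned by [assemble_dataset()].
#' @param t Optional vector of seconds since session start. Must be strictly
#'   increasing with constant step `1 / sample_rate` (relative tolerance
#'   `1e-9`).
#'
#' @return A tibble of class `insole_recording` with columns `t`, `f_heel`,
#'   `f_mid`, `f_fore` and the session metadata stored as attributes
#'   (retrieve with [recording_meta()]).
#' @seealso [read_recording()], [write_recording()], [assemble_dataset()]
#' @export
#' @examples
#' rec <- insole_recording(
#'   f_heel = c(0, 10, 0, 0), f_mid = c(0, 0, 5, 0), f_fore = c(0, 0, 0, 7),
#'   participant_id = "P01", session_id = "S01",
#'   start_time = as.POSIXct("2026-01-05 08:00:00", tz = "UTC")
#' )
#' recording_duration(rec)
insole_recording <- function(f_heel, f_mid, f_fore,
                             participant_id, session_id,
                             start_time, sample_rate = 20,
                             day_index = NA_integer_, t = NULL) {
  n <- length(f_heel)
  if (n == 0L) {
    stop_tendonload("recording has no samples", "empty_input")
  }
  if (length(f_mid) != n || length(f_fore) != n) {
    stop_tendonload("force channels must have equal length", "integrity")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop_tendonload("sample_rate must be a positive number", "domain")
  }
  if (!is.na(day_index) && day_index < 1) {
    stop_tendonload("day_index must be >= 1", "domain")
  }
  if (anyNA(f_heel) || anyNA(f_mid) || anyNA(f_fore) ||
      !all(is.finite(f_heel)) || !all(is.finite(f_mid)) ||
      !all(is.finite(f_fore))) {
    stop_tendonload("forces must be finite", "domain")
  }
  if (!is.null(t)) {
    if (length(t) != n) {
      stop_tendonload("t must match channel length", "integrity")
    }
    if (n > 1L) {
      dt <- diff(t)
      if (any(dt <= 0)) {
        stop_tendonload("timestamps are not strictly increasing", "integrity")
      }
      step <- 1 / sample_rate
      if (any(abs(dt - step) > 1e-9 * step + 1e-12)) {
        stop_tendonload(
          "timestamps are not uniform at 1/sample_rate", "integrity")
      }
    }
  }
  sample_rate <- as.double(sample_rate)
  out <- tibble::tibble(
    t = (seq_len(n) - 1) / sample_rate,
    f_heel = as.double(f_heel),
    f_mid = as.double(f_mid),
    f_fore = as.double(f_fore)
  )
  new_insole_recording(out,
    participant_id = as.character(participant_id),
    session_id = as.character(session_id),
    start_time = start_time,
    sample_rate = sample_rate,
    day_index = as.integer(day_index)
  )
}

new_insole_recording <- function(df, participant_id, session_id, start_time,
                                 sample_rate, day_index) {
  structure(
    df,
    participant_id = participant_id,
    session_id = session_id,
    start_time = start_time,
    sample_rate = sample_rate,
    day_index = day_index,
    class = c("insole_recording", class(tibble::tibble()))
  )
}

#' Session metadata of a recording or load trace
#'
#' @param x An `insole_recording` or `tendon_load_trace`.
#' @return A one-row tibble with `participant_id`, `session_id`,
#'   `start_time`, `sample_rate` and `day_index`.
#' @export
recording_meta <- function(x) {
  tibble::tibble(
    participant_id = attr(x, "participant_id"),
    session_id = attr(x, "session_id"),
    start_time = attr(x, "start_time"),
    sample_rate = attr(x, "sample_rate"),
    day_index = attr(x, "day_index")
  )
}

#' @rdname recording_meta
#' @export
sample_rate <- function(x) attr(x, "sample_rate")

#' Duration of a recording in seconds
#'
#' Duration is the sampled span `n / sample_rate`, counting each sample as
#' one sampling period.
#'
#' @param x An `insole_recording` or `tendon_load_trace`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(x) nrow(x) / attr(x, "sample_rate")

#' Total (summed-channel) force of a recording
#'
#' @param rec An `insole_recording`.
#' @return Numeric vector of per-sample total plantar force in Newtons.
#' @export
total_force <- function(rec) rec$f_heel + rec$f_mid + rec$f_fore

with_recording_forces <- function(rec, f_heel, f_mid, f_fore) {
  rec$f_heel <- f_heel
  rec$f_mid <- f_mid
  rec$f_fore <- f_fore
  rec
}

#' Construct a participant profile
#'
#' Anthropometrics and survey scores for one participant. Body weight is
#' derived as `mass * g` with standard gravity `g = 9.80665` m/s^2 and is the
#' normalization constant for tendon load (`xBW` units).
#'
#' @param participant_id Character scalar.
#' @param mass Body mass in kg (> 0).
#' @param height Body height in m (> 0).
#' @param age Age in years.
#' @param sex Character, e.g. `"F"`/`"M"`.
#' @param symptomatic_side Character, `"left"`/`"right"`/`"bilateral"`.
#' @param visa_a VISA-A questionnaire score, 0-100 (100 = asymptomatic).
#' @param pas Physical Activity Scale, integer 1-6.
#'
#' @return A one-row tibble including the derived `body_weight` in Newtons.
#' @export
#' @examples
#' participant_profile("P01", mass = 80, height = 1.75, visa_a = 60, pas = 4)
participant_profile <- function(participant_id, mass, height,
                                age = NA_real_, sex = NA_character_,
                                symptomatic_side = NA_character_,
                                visa_a = NA_real_, pas = NA_integer_) {
  if (!is.finite(mass) || mass <= 0) {
    stop_tendonload("mass must be > 0", "domain")
  }
  if (!is.finite(height) || height <= 0) {
    stop_tendonload("height must be > 0", "domain")
  }
  if (!is.na(visa_a) && (visa_a < 0 || visa_a > 100)) {
    stop_tendonload("visa_a must lie in [0, 100]", "domain")
  }
  if (!is.na(pas) && !(pas %in% 1:6)) {
    stop_tendonload("pas must be an integer in 1..6", "domain")
  }
  tibble::tibble(
    participant_id = as.character(participant_id),
    mass = mass,
    height = height,
    body_weight = mass * GRAVITY,
    age = age,
    sex = sex,
    symptomatic_side = symptomatic_side,
    visa_a = visa_a,
    pas = as.integer(pas)
  )
}

recording_csv_columns <- c("time_s", "f_heel_n", "f_mid_n", "f_fore_n")

# 17 significant digits: lossless text representation of a double
fmt_double <- function(x) sprintf("%.17g", x)

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read an insole recording from the project dialect
#'
#' Reads one session from a CSV of samples (`time_s`, `f_heel_n`, `f_mid_n`,
#' `f_fore_n`) plus a JSON sidecar (same path with extension `.json`)
#' carrying `participant_id`, `session_id`, `start_time` (ISO 8601),
#' `sample_rate` and optionally `day_index`. Timestamps are regularized to
#' the nominal rate; out-of-order rows are rejected.
#'
#' @param path Path to the session CSV.
#' @return An [insole_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) {
    stop_tendonload(paste0("no such recording: ", path), "format")
  }
  # base read.csv: strtod parsing is correctly rounded, so the 17-digit
  # dialect round-trips doubles exactly
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) {
    stop_tendonload(paste0("empty recording file: ", path), "empty_input")
  }
  missing <- setdiff(recording_csv_columns, names(df))
  if (length(missing) > 0L) {
    stop_tendonload(
      paste0("recording file is missing column(s): ",
             paste(missing, collapse = ", ")),
      "format")
  }
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop_tendonload(paste0("missing metadata sidecar: ", side), "format")
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (field in c("participant_id", "session_id", "start_time",
                  "sample_rate")) {
    if (is.null(meta[[field]])) {
      stop_tendonload(paste0("sidecar is missing field: ", field), "format")
    }
  }
  insole_recording(
    f_heel = df$f_heel_n, f_mid = df$f_mid_n, f_fore = df$f_fore_n,
    participant_id = meta$participant_id,
    session_id = meta$session_id,
    start_time = as.POSIXct(meta$start_time, tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%S"),
    sample_rate = meta$sample_rate,
    day_index = meta$day_index %||% NA_integer_,
    t = df$time_s
  )
}

#' Write an insole recording in the project dialect
#'
#' Inverse of [read_recording()]: emits the sample CSV and the JSON metadata
#' sidecar. Doubles are written in shortest round-trippable form, so
#' `read_recording(write_recording(rec, path))` reproduces every sample
#' exactly.
#'
#' @param rec An [insole_recording()].
#' @param path Destination CSV path (sidecar written alongside).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- tibble::tibble(
    time_s = fmt_double(rec$t),
    f_heel_n = fmt_double(rec$f_heel),
    f_mid_n = fmt_double(rec$f_mid),
    f_fore_n = fmt_double(rec$f_fore)
  )
  readr::write_csv(df, path, progress = FALSE)
  meta <- recording_meta(rec)
  jsonlite::write_json(
    list(
      participant_id = meta$participant_id,
      session_id = meta$session_id,
      start_time = format(meta$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      sample_rate = meta$sample_rate,
      day_index = meta$day_index
    ),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Assemble a participant's recordings into a day-grouped dataset
#'
#' Orders a participant's sessions by start time, assigns each a 1-based
#' `day_index` from the calendar date of its start time (day 1 = first
#' recorded date; a session spanning midnight stays with its start date),
#' and reports the wear-day count (days with at least one recording).
#'
#' @param recordings List of [insole_recording()] objects sharing one
#'   `participant_id`.
#' @param profile A [participant_profile()] row for the same participant.
#' @return A list of class `participant_dataset`: `profile`, `recordings`
#'   (ordered, with `day_index` assigned), `days` (tibble of `day_index`,
#'   `date`, `n_sessions`) and `wear_days`.
#' @export
assemble_dataset <- function(recordings, profile) {
  if (length(recordings) == 0L) {
    out <- list(
      profile = profile,
      recordings = list(),
      days = tibble::tibble(day_index = integer(), date = as.Date(character()),
                            n_sessions = integer()),
      wear_days = 0L
    )
    class(out) <- "participant_dataset"
    return(out)
  }
  ids <- vapply(recordings, function(r) attr(r, "participant_id"), "")
  if (length(unique(ids)) > 1L) {
    stop_tendonload("recordings mix multiple participant_ids", "integrity")
  }
  if (ids[[1L]] != profile$participant_id) {
    stop_tendonload("recordings do not match the supplied profile",
                    "integrity")
  }
  sessions <- vapply(recordings, function(r) attr(r, "session_id"), "")
  if (anyDuplicated(sessions)) {
    stop_tendonload("duplicate session_id in recordings", "integrity")
  }
  starts <- do.call(c, lapply(recordings, function(r) attr(r, "start_time")))
  ord <- order(starts)
  recordings <- recordings[ord]
  starts <- starts[ord]
  dates <- as.Date(starts, tz = "UTC")
  day_index <- as.integer(dates - min(dates)) + 1L
  recordings <- purrr::map2(recordings, day_index, function(r, d) {
    attr(r, "day_index") <- d
    r
  })
  days <- tibble::tibble(day_index = day_index, date = dates) |>
    dplyr::count(.data$day_index, .data$date, name = "n_sessions")
  out <- list(
    profile = profile,
    recordings = recordings,
    days = days,
    wear_days = nrow(days)
  )
  class(out) <- "participant_dataset"
  out
}

#' @export
print.participant_dataset <- function(x, ...) {
  cat(sprintf(
    "<participant_dataset> %s: %d session(s) over %d wear day(s)\n",
    x$profile$participant_id, length(x$recordings), x$wear_days))
  invisible(x)
}
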