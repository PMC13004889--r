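# Synthetic cohort generator. Waveform realism is deliberately secondary to
# analytic tractability: days are assembled from pulse-parametric bouts
# (raised-cosine stance pulses for gait, constant-plus-sway for standing,
# zeros for rest) whose supra-threshold time and impulse have closed forms,
# so every participant carries exact ground truth for the cumulative load
# biomarkers. Forces are then synthesized by inverting the moment-arm model
# with a stance-phase heel-to-forefoot progression, and measurement
# artifacts (noise, offsets, step drifts, initialization failures) are
# injected on top.

#' Artifact specification for the synthetic generator
#'
#' Magnitudes and probabilities of the injected measurement artifacts.
#' These mimic the failure modes of real insole recordings: white sensor
#' noise, a constant initialization offset on one channel, a mid-session
#' step drift, and (rarely) an initialization failure in which the baseline
#' wanders for the whole session and the sensor never reads quiet -- such
#' sessions are unrecoverable and should be screened out by QC.
#'
#' @param enabled Master switch; when `FALSE` recordings are returned
#'   unmodified.
#' @param noise_sd_n White noise SD per channel (N).
#' @param offset_prob,offset_n Probability / magnitude of a whole-session
#'   constant offset on one random channel.
#' @param step_drift_prob,step_drift_n Probability / magnitude of a step
#'   drift starting at a uniform random time on one random channel. A step
#'   that begins mid-activity stays uncorrected until the next quiet
#'   baseline anchor, so the default magnitude is kept within the band that
#'   shifts tendon load by well under the margin between ordinary walking
#'   peaks and the high-level threshold.
#' @param init_failure_prob Probability that a session is an initialization
#'   failure (wandering baseline, never unloaded).
#' @param wander_sd_n Innovation SD of the AR(1) baseline wander used for
#'   initialization failures.
#' @return A list of class `artifact_spec`.
#' @export
artifact_spec <- function(enabled = TRUE, noise_sd_n = 1.5,
                          offset_prob = 0.3, offset_n = 40,
                          step_drift_prob = 0.25, step_drift_n = 15,
                          init_failure_prob = 0.03, wander_sd_n = 3) {
  probs <- c(offset_prob, step_drift_prob, init_failure_prob)
  if (any(probs < 0 | probs > 1)) {
    stop_tendonload("artifact probabilities must lie in [0, 1]", "config")
  }
  structure(
    list(enabled = enabled, noise_sd_n = noise_sd_n,
         offset_prob = offset_prob, offset_n = offset_n,
         step_drift_prob = step_drift_prob, step_drift_n = step_drift_n,
         init_failure_prob = init_failure_prob, wander_sd_n = wander_sd_n),
    class = "artifact_spec")
}

default_outcome_targets <- function() {
  c(peak_moment_isometric = 0.48, peak_moment_iso30 = 0.50,
    peak_moment_iso150 = 0.62, peak_power_iso30 = 0.52,
    peak_power_iso150 = 0.59, work_iso30 = 0.48, work_iso150 = 0.47,
    heel_raise_height = 0.69, cmj_height = 0.55, incline_reps = 0.30,
    age = -0.33, visa_a = 0.44, pas = 0.62)
}

#' Scenario configuration for the synthetic cohort
#'
#' Defines the study conditions the generator emulates: a cohort monitored
#' for 6-14 days at 20 Hz, each wear day mixing walking bouts peaking near
#' 3xBW (the approximate peak tendon load of walking), quiet standing near
#' 0.5xBW with postural sway, rest, and -- on a subset of days -- dynamic
#' exercise (a run with ~5xBW peaks and a set of heel raises at 4xBW)
#' that alone drives loading beyond the 3xBW high-level threshold.
#' Participant-level outcome measures are drawn with configurable target
#' Pearson correlations to the ground-truth normalized high-level load
#' (a linear mix of the standardized load with independent noise).
#'
#' @param n_participants Cohort size.
#' @param days_range Integer range of monitoring days per participant.
#' @param sample_rate Hz.
#' @param walking List: `step_period_s` (per-foot stride period),
#'   `stance_fraction`, `peak_bw` and `peak_sd_bw` (mean and step-to-step
#'   SD of the stance-pulse peak; the default mean sits just below the
#'   3xBW threshold so that ordinary walking only occasionally grazes it),
#'   `minutes_per_day`, `swing_jitter` (relative jitter of swing gaps,
#'   which also decorrelates pulse phase from the sampling grid).
#' @param standing List: `level_bw`, `sway_bw`, `sway_period_s`,
#'   `minutes_per_day`.
#' @param rest_minutes_per_day Zero-force minutes interleaved as quiet
#'   baseline anchors.
#' @param exercise List: `mode` (`"bernoulli"` days with probability
#'   `prob_day`; `"one-of-first-6"` exactly one random day among the first
#'   six; `"none"`), `prob_day`, `run` (step_period_s, stance_fraction,
#'   peak_bw, minutes) and `raises` (reps, period_s, duty, peak_bw).
#' @param wear_cv Day-to-day coefficient of variation of walking/standing
#'   minutes.
#' @param artifacts An [artifact_spec()].
#' @param outcome_targets Named numeric of target Pearson correlations
#'   between ground-truth normalized high-level load and each outcome
#'   measure (each within -1..1).
#' @param thresholds Named numeric `c(overall =, high =)` in xBW.
#' @param seed Integer seed; the same config (including seed) always
#'   reproduces the identical cohort.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_participants = 15,
                            days_range = c(6L, 14L),
                            sample_rate = 20,
                            walking = list(step_period_s = 1.17,
                                           stance_fraction = 0.58,
                                           peak_bw = 2.8,
                                           peak_sd_bw = 0.06,
                                           minutes_per_day = 30,
                                           swing_jitter = 0.3),
                            standing = list(level_bw = 0.5,
                                            sway_bw = 0.12,
                                            sway_period_s = 4,
                                            minutes_per_day = 25),
                            rest_minutes_per_day = 4,
                            exercise = list(mode = "bernoulli",
                                            prob_day = 0.4,
                                            run = list(step_period_s = 0.72,
                                                       stance_fraction = 0.35,
                                                       peak_bw = 5.0,
                                                       minutes = 20),
                                            raises = list(reps = 15,
                                                          period_s = 2.0,
                                                          duty = 0.6,
                                                          peak_bw = 4.0)),
                            wear_cv = 0.2,
                            artifacts = artifact_spec(),
                            outcome_targets = default_outcome_targets(),
                            thresholds = default_thresholds(),
                            seed = 1L) {
  if (any(abs(outcome_targets) > 1)) {
    stop_tendonload("outcome correlation targets must lie in [-1, 1]",
                    "config")
  }
  if (walking$peak_bw < 0 || exercise$run$peak_bw < 0 ||
      exercise$raises$peak_bw < 0 || standing$level_bw < 0) {
    stop_tendonload("peak loads must be >= 0", "domain")
  }
  if (days_range[1] < 1 || days_range[2] < days_range[1]) {
    stop_tendonload("invalid days_range", "config")
  }
  structure(
    list(n_participants = n_participants, days_range = as.integer(days_range),
         sample_rate = sample_rate, walking = walking, standing = standing,
         rest_minutes_per_day = rest_minutes_per_day, exercise = exercise,
         wear_cv = wear_cv, artifacts = artifacts,
         outcome_targets = outcome_targets, thresholds = thresholds,
         seed = as.integer(seed)),
    class = "scenario_config")
}

# ---- segment primitives and closed-form bookkeeping ----------------------

seg_rest <- function(duration_s) {
  list(type = "rest", duration_s = duration_s)
}

seg_constant <- function(duration_s, level_bw, sway_bw = 0,
                         sway_period_s = 4, phase = 0) {
  # duration is rounded to whole sway periods so the closed-form supra-
  # threshold time/impulse are independent of phase
  if (sway_bw > 0) {
    duration_s <- max(sway_period_s, round(duration_s / sway_period_s) *
                        sway_period_s)
  }
  list(type = "constant", duration_s = duration_s, level_bw = level_bw,
       sway_bw = sway_bw, sway_period_s = sway_period_s, phase = phase)
}

seg_pulses <- function(peak_bw, stance_s, gaps_s, lead_s = 0) {
  if (any(peak_bw < 0)) stop_tendonload("pulse peak must be >= 0", "domain")
  n <- length(gaps_s)
  peak_bw <- rep_len(peak_bw, n)
  list(type = "pulses", peak_bw = peak_bw, stance_s = stance_s,
       gaps_s = gaps_s, lead_s = lead_s,
       duration_s = lead_s + n * stance_s + sum(gaps_s))
}

# time (s) and impulse (xBW*s) at/above thr, summed over raised-cosine
# pulses of peaks P and stance duration d:
# load(u) = P/2 * (1 - cos(2*pi*u/d))
pulse_book <- function(P, d, thr) {
  P <- P[P > 0]
  if (length(P) == 0L) return(c(time = 0, impulse = 0))
  if (thr <= 0) {
    return(c(time = length(P) * d, impulse = sum(P) * d / 2))
  }
  P <- P[P > thr]
  if (length(P) == 0L) return(c(time = 0, impulse = 0))
  theta0 <- acos(1 - 2 * thr / P)
  time <- d * (1 - theta0 / pi)
  impulse <- P * d / (4 * pi) * (2 * pi - 2 * theta0 + 2 * sin(theta0))
  c(time = sum(time), impulse = sum(impulse))
}

# constant level L with sinusoidal sway amplitude A over whole periods
constant_book <- function(L, A, D, thr) {
  if (A <= 0) {
    if (L >= thr && D > 0) return(c(time = D, impulse = L * D))
    return(c(time = 0, impulse = 0))
  }
  cc <- (thr - L) / A
  if (cc <= -1) return(c(time = D, impulse = L * D))
  if (cc >= 1) return(c(time = 0, impulse = 0))
  f <- 0.5 - asin(cc) / pi
  c(time = D * f, impulse = D * (L * f + A * sqrt(1 - cc^2) / pi))
}

segment_book <- function(seg, thr) {
  switch(seg$type,
    rest = c(time = 0, impulse = 0),
    constant = constant_book(seg$level_bw, seg$sway_bw, seg$duration_s, thr),
    pulses = pulse_book(seg$peak_bw, seg$stance_s, thr),
    stop_tendonload(paste0("unknown segment type: ", seg$type), "config"))
}

segment_samples <- function(seg, tau) {
  switch(seg$type,
    rest = numeric(length(tau)),
    constant = {
      sway <- if (seg$sway_bw > 0) {
        seg$sway_bw * sin(2 * pi * tau / seg$sway_period_s + seg$phase)
      } else 0
      seg$level_bw + sway
    },
    pulses = {
      n <- length(seg$gaps_s)
      starts <- seg$lead_s +
        c(0, cumsum(seg$stance_s + seg$gaps_s))[seq_len(n)]
      m <- findInterval(tau, starts)
      u <- tau - c(-Inf, starts)[m + 1L]
      val <- numeric(length(tau))
      in_stance <- m >= 1L & u < seg$stance_s
      val[in_stance] <- seg$peak_bw[m[in_stance]] / 2 *
        (1 - cos(2 * pi * u[in_stance] / seg$stance_s))
      val
    })
}

#' Generate a tendon load waveform with exact bookkeeping
#'
#' Samples a piecewise waveform (see `seg_rest()`, `seg_constant()`,
#' `seg_pulses()` builders, or pass pre-built segment lists) on the uniform
#' grid and returns, alongside the sampled trace, the *continuous-time*
#' supra-threshold time and impulse of the waveform computed in closed form
#' from the segment parameters -- the ground truth that the discrete
#' pipeline is later checked against.
#'
#' @param segments List of segment specifications, in temporal order.
#' @param sample_rate Hz.
#' @param thresholds Named numeric of load thresholds (xBW).
#' @return A list: `load` (xBW per sample), `t` (s), `duration_s`, and
#'   `bookkeeping` -- a tibble with one row per threshold (`threshold`,
#'   `time_above_h`, `impulse_above_bwh`).
#' @export
#' @examples
#' wf <- generate_load_waveform(list(seg_constant(36, 2)), 20)
#' wf$bookkeeping # 0.02 xBW*h at both default thresholds
generate_load_waveform <- function(segments, sample_rate = 20,
                                   thresholds = default_thresholds()) {
  durs <- vapply(segments, `[[`, 0, "duration_s")
  if (any(durs < 0)) stop_tendonload("segment durations must be >= 0",
                                     "domain")
  total <- sum(durs)
  n <- floor(total * sample_rate + 1e-9)
  t <- (seq_len(n) - 1) / sample_rate
  load <- numeric(n)
  bounds <- cumsum(c(0, durs))
  for (j in seq_along(segments)) {
    if (durs[j] == 0) next
    idx <- which(t >= bounds[j] & t < bounds[j + 1])
    if (length(idx) > 0L) {
      load[idx] <- segment_samples(segments[[j]], t[idx] - bounds[j])
    }
  }
  book <- purrr::imap(thresholds, function(thr, nm) {
    acc <- c(time = 0, impulse = 0)
    for (seg in segments) acc <- acc + segment_book(seg, thr)
    tibble::tibble(threshold = unname(thr),
                   time_above_h = unname(acc[["time"]]) / 3600,
                   impulse_above_bwh = unname(acc[["impulse"]]) / 3600)
  }) |> dplyr::bind_rows()
  book$name <- names(thresholds)
  list(load = load, t = t, duration_s = total, bookkeeping = book)
}

# ---- force synthesis (model inversion) -----------------------------------

stance_shares <- function(p) {
  w_h <- 0.45 * (1 - p)^2
  w_m <- 0.30 * sin(pi * p) + 0.05
  w_f <- 0.55 * p^2 + 0.10
  tot <- w_h + w_m + w_f
  cbind(heel = w_h / tot, mid = w_m / tot, fore = w_f / tot)
}

#' Synthesize sensor forces that reproduce a load waveform
#'
#' Inverts the moment-arm model: distributes plantar force across the three
#' sensor pads with a heel-to-forefoot progression over each contiguous
#' loaded run (mimicking center-of-pressure travel during stance), scaled so
#' that applying [estimate_trace()] to the output recovers the input load
#' trace at every sample. The share schedule keeps the effective moment arm
#' positive, so the recovery is exact up to floating point.
#'
#' @param load Numeric vector of tendon load (xBW) per sample.
#' @param geom A [sensor_geometry()].
#' @param profile A [participant_profile()] (for body weight).
#' @param participant_id,session_id,start_time,sample_rate,day_index
#'   Session metadata for the resulting recording.
#' @return An [insole_recording()].
#' @export
waveform_to_forces <- function(load, geom = sensor_geometry(), profile,
                               participant_id = profile$participant_id,
                               session_id = "S01",
                               start_time = as.POSIXct("2026-03-02 08:00:00",
                                                       tz = "UTC"),
                               sample_rate = 20, day_index = NA_integer_) {
  n <- length(load)
  pos <- load > 0
  p <- numeric(n)
  if (any(pos)) {
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      len <- r$lengths[j]
      p[starts[j]:ends[j]] <- if (len == 1L) 0.5 else {
        (seq_len(len) - 1) / (len - 1)
      }
    }
  }
  sh <- stance_shares(p)
  arm_eff <- sh[, "heel"] * geom$r_heel + sh[, "mid"] * geom$r_mid +
    sh[, "fore"] * geom$r_fore
  f_tot <- ifelse(pos, load * profile$body_weight * geom$r_at / arm_eff, 0)
  insole_recording(
    f_heel = sh[, "heel"] * f_tot,
    f_mid = sh[, "mid"] * f_tot,
    f_fore = sh[, "fore"] * f_tot,
    participant_id = participant_id, session_id = session_id,
    start_time = start_time, sample_rate = sample_rate,
    day_index = day_index
  )
}

# ---- artifact injection --------------------------------------------------

#' Inject measurement artifacts into a recording
#'
#' Deterministically (given `seed`) adds white sensor noise, with the
#' configured probabilities a constant initialization offset on one random
#' channel, a mid-session step drift, and -- for initialization-failure
#' sessions -- an AR(1) baseline wander on every channel that keeps the
#' session from ever reading quiet, so that screening excludes it.
#'
#' @param rec An [insole_recording()].
#' @param spec An [artifact_spec()]; with `enabled = FALSE` (or all
#'   magnitudes zero) the recording is returned unchanged.
#' @param seed Integer seed for the artifact draws.
#' @return The recording with artifacts added; the draws are recorded in
#'   the `artifact_log` attribute (a one-row tibble with `init_failure`,
#'   offset/drift channels and magnitudes).
#' @export
inject_artifacts <- function(rec, spec = artifact_spec(), seed = 1L) {
  log <- tibble::tibble(
    session_id = attr(rec, "session_id"), noise_sd_n = 0,
    offset_channel = NA_character_, offset_n = 0,
    drift_channel = NA_character_, drift_n = 0, drift_onset_s = NA_real_,
    init_failure = FALSE)
  if (!spec$enabled) {
    attr(rec, "artifact_log") <- log
    return(rec)
  }
  set.seed(seed)
  channels <- c("f_heel", "f_mid", "f_fore")
  n <- nrow(rec)
  fs <- sample_rate(rec)

  if (spec$noise_sd_n > 0) {
    for (ch in channels) {
      rec[[ch]] <- rec[[ch]] + rnorm(n, sd = spec$noise_sd_n)
    }
    log$noise_sd_n <- spec$noise_sd_n
  }
  if (runif(1) < spec$offset_prob && spec$offset_n > 0) {
    ch <- sample(channels, 1L)
    mag <- spec$offset_n * runif(1, 0.5, 1)
    rec[[ch]] <- rec[[ch]] + mag
    log$offset_channel <- ch
    log$offset_n <- mag
  }
  if (runif(1) < spec$step_drift_prob && spec$step_drift_n > 0) {
    ch <- sample(channels, 1L)
    mag <- spec$step_drift_n * runif(1, 0.5, 1)
    onset <- floor(runif(1, 0.2, 0.8) * n)
    rec[[ch]][(onset + 1L):n] <- rec[[ch]][(onset + 1L):n] + mag
    log$drift_channel <- ch
    log$drift_n <- mag
    log$drift_onset_s <- onset / fs
  }
  if (runif(1) < spec$init_failure_prob && spec$wander_sd_n > 0) {
    # AR(1) random walk plus a slow oscillation so that no 10-s epoch of
    # the session ever reads quiet -- the never-unloaded signature
    tt <- (seq_len(n) - 1) / fs
    for (ch in channels) {
      innov <- rnorm(n, sd = spec$wander_sd_n)
      wander <- as.numeric(stats::filter(innov, 0.999,
                                         method = "recursive"))
      wander <- wander + 30 * sin(2 * pi * tt / 7 + runif(1, 0, 2 * pi))
      rec[[ch]] <- rec[[ch]] + wander
    }
    log$init_failure <- TRUE
  }
  attr(rec, "artifact_log") <- log
  rec
}

# ---- cohort generation ---------------------------------------------------

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- x < lower | x > upper
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lower | x > upper
  }
  x
}

day_segments <- function(cfg, exercise_today, rng_mult) {
  # rng_mult: multipliers for walking minutes, standing minutes and run
  # minutes (participant-level habits times day-level variation)
  wk <- cfg$walking
  st <- cfg$standing
  walk_s <- wk$minutes_per_day * 60 * rng_mult[1]
  stand_s <- st$minutes_per_day * 60 * rng_mult[2]
  rest_s <- cfg$rest_minutes_per_day * 60

  walking_bout <- function(seconds) {
    n <- max(1L, round(seconds / wk$step_period_s))
    g0 <- wk$step_period_s * (1 - wk$stance_fraction)
    gaps <- pmax(0.05, g0 * (1 + wk$swing_jitter * (runif(n) - 0.5)))
    peak_sd <- wk$peak_sd_bw %||% 0
    # step peaks vary but are physiologically bounded (+/- 2.5 SD)
    peaks <- pmin(wk$peak_bw + 2.5 * peak_sd,
                  pmax(wk$peak_bw - 2.5 * peak_sd,
                       rnorm(n, wk$peak_bw, peak_sd)))
    seg_pulses(peaks, wk$step_period_s * wk$stance_fraction, gaps,
               lead_s = runif(1, 0, g0))
  }
  standing_bout <- function(seconds) {
    seg_constant(seconds, st$level_bw, st$sway_bw, st$sway_period_s,
                 phase = runif(1, 0, 2 * pi))
  }
  segs <- list(
    seg_rest(rest_s / 3),
    walking_bout(walk_s / 2),
    standing_bout(stand_s / 2),
    seg_rest(rest_s / 3),
    walking_bout(walk_s / 2),
    standing_bout(stand_s / 2)
  )
  if (exercise_today) {
    run <- cfg$exercise$run
    raises <- cfg$exercise$raises
    run_minutes <- run$minutes * rng_mult[3]
    if (run_minutes > 0) {
      n <- max(1L, round(run_minutes * 60 / run$step_period_s))
      g0 <- run$step_period_s * (1 - run$stance_fraction)
      gaps <- pmax(0.03, g0 * (1 + 0.3 * (runif(n) - 0.5)))
      segs <- c(segs, list(
        seg_pulses(run$peak_bw * runif(1, 0.95, 1.05),
                   run$step_period_s * run$stance_fraction, gaps,
                   lead_s = runif(1, 0, g0))))
    }
    if (raises$reps > 0) {
      g0 <- raises$period_s * (1 - raises$duty)
      gaps <- rep(g0, raises$reps)
      segs <- c(segs, list(
        seg_pulses(raises$peak_bw, raises$period_s * raises$duty, gaps,
                   lead_s = runif(1, 0, g0))))
    }
  }
  c(segs, list(seg_rest(rest_s / 3)))
}

outcome_scales <- function() {
  tibble::tribble(
    ~measure, ~mean, ~sd, ~kind,
    "peak_moment_isometric", 9.0, 2.5, "continuous",
    "peak_moment_iso30", 7.5, 2.0, "continuous",
    "peak_moment_iso150", 5.5, 1.8, "continuous",
    "peak_power_iso30", 4.0, 1.2, "continuous",
    "peak_power_iso150", 14.0, 4.0, "continuous",
    "work_iso30", 5.0, 1.5, "continuous",
    "work_iso150", 3.5, 1.2, "continuous",
    "heel_raise_height", 5.5, 1.5, "continuous",
    "cmj_height", 8.0, 3.0, "continuous",
    "incline_reps", 14, 6, "count",
    "age", 47, 12, "age",
    "visa_a", 54, 26, "visa",
    "pas", 3.8, 1.6, "pas"
  )
}

# Construction of participant-level outcome measures with a target Pearson
# correlation to the ground-truth normalized high-level load: each outcome
# is a rho-weighted mix of the standardized load values with independent
# standardized noise (so the target correlation is met on the raw Pearson
# scale, not just in rank), then affinely rescaled -- and discretized for
# count/ordinal measures, which attenuates the correlation slightly.
draw_outcomes <- function(norm_high, targets, seed) {
  n <- length(norm_high)
  set.seed(seed)
  z <- as.numeric(scale(norm_high))
  scales <- outcome_scales()
  measures <- tibble::tibble(
    participant_id = names(norm_high) %||% as.character(seq_len(n)))
  for (m in names(targets)) {
    rho <- targets[[m]]
    eps <- rnorm(n)
    # orthogonalize the noise against the load scores so the realized
    # correlation equals the target exactly before discretization
    eps <- eps - z * sum(eps * z) / sum(z * z)
    y <- rho * z + sqrt(1 - rho^2) * as.numeric(scale(eps))
    sc <- scales[scales$measure == m, ]
    if (nrow(sc) == 0L) sc <- tibble::tibble(mean = 0, sd = 1,
                                             kind = "continuous")
    val <- switch(sc$kind,
      continuous = pmax(0, sc$mean + sc$sd * y),
      count = pmax(0, round(sc$mean + sc$sd * y)),
      age = pmin(70, pmax(18, round(sc$mean + sc$sd * y))),
      visa = pmin(100, pmax(0, round(sc$mean + sc$sd * y))),
      pas = as.integer(pmin(6, pmax(1, round(sc$mean + sc$sd * y)))))
    measures[[m]] <- val
  }
  measures
}

#' Generate a synthetic insole-monitoring cohort
#'
#' Produces, deterministically for a given config, the full inputs of the
#' analysis pipeline plus exact ground truth: per-day recordings (forces
#' synthesized by inverting the moment-arm model, artifacts injected),
#' participant profiles, participant-level functional/survey outcome
#' measures drawn with the configured target correlations to ground-truth
#' normalized high-level load, and closed-form bookkeeping of every
#' cumulative biomarker. Sessions struck by an initialization-failure
#' artifact are unrecoverable by design and are excluded from the ground
#' truth (QC screening is expected to remove exactly these).
#'
#' @param config A [scenario_config()].
#' @return A list of class `synthetic_cohort`: `recordings` (list of
#'   [insole_recording()]), `profiles`, `measures`, `ground_truth` (list
#'   with `participants` and `days` tibbles), `artifact_logs`, `config`.
#' @export
generate_cohort <- function(config = scenario_config()) {
  n <- config$n_participants
  thr <- config$thresholds
  recordings <- list()
  artifact_logs <- list()
  gt_days <- list()
  profiles <- list()
  base_date <- as.POSIXct("2026-03-02 08:00:00", tz = "UTC")

  for (i in seq_len(n)) {
    pseed <- config$seed + i * 1009L
    set.seed(pseed)
    pid <- sprintf("P%02d", i)
    mass <- rtrunc_norm(1, 95.6, 24.9, 59, 141)
    height <- rtrunc_norm(1, 1.72, 0.12, 1.55, 1.91)
    sex <- sample(c("F", "M"), 1L)
    side <- sample(c("left", "right", "bilateral"), 1L)
    profile <- participant_profile(pid, mass = mass, height = height,
                                   sex = sex, symptomatic_side = side)
    days_seq <- seq(config$days_range[1], config$days_range[2])
    n_days <- days_seq[sample.int(length(days_seq), 1L)]
    ex_mode <- config$exercise$mode
    ex_days <- switch(ex_mode,
      "bernoulli" = {
        # wide propensity spread: some participants exercise most days,
        # others hardly ever (mean prob_day across the cohort)
        prob_i <- rbeta(1, 1.2, 1.8) * config$exercise$prob_day / 0.4
        runif(n_days) < min(1, prob_i)
      },
      "one-of-first-6" = {
        d <- sample(1:6, 1L)
        seq_len(n_days) == d
      },
      "none" = rep(FALSE, n_days),
      stop_tendonload("unknown exercise mode", "config"))

    # persistent habits: participants differ in how much they walk, stand
    # and run, on top of day-to-day variation
    habit <- c(runif(1, 0.35, 1.65), runif(1, 0.5, 1.5),
               runif(1, 0.4, 1.6))

    for (d in seq_len(n_days)) {
      mult <- habit * pmax(0.3, 1 + config$wear_cv * rnorm(3))
      segs <- day_segments(config, ex_days[d], mult)
      wf <- generate_load_waveform(segs, config$sample_rate, thr)
      rec <- waveform_to_forces(
        wf$load, geom = sensor_geometry(), profile = profile,
        session_id = sprintf("%s_D%02d", pid, d),
        start_time = base_date + (d - 1) * 86400,
        sample_rate = config$sample_rate, day_index = d)
      rec <- inject_artifacts(rec, config$artifacts,
                              seed = pseed + 500L + d)
      log <- attr(rec, "artifact_log")
      recordings[[length(recordings) + 1L]] <- rec
      artifact_logs[[length(artifact_logs) + 1L]] <- log
      bk <- wf$bookkeeping
      gt_days[[length(gt_days) + 1L]] <- tibble::tibble(
        participant_id = pid, day_index = d,
        exercise = ex_days[d],
        init_failure = log$init_failure,
        loading_time_h = bk$time_above_h[bk$name == "overall"],
        high_time_h = bk$time_above_h[bk$name == "high"],
        overall_impulse_bwh = bk$impulse_above_bwh[bk$name == "overall"],
        high_impulse_bwh = bk$impulse_above_bwh[bk$name == "high"])
    }
    profiles[[i]] <- profile
  }

  gt_days <- dplyr::bind_rows(gt_days)
  gt_participants <- gt_days |>
    dplyr::filter(!.data$init_failure) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_days_valid = dplyr::n(),
      loading_time_h = sum(.data$loading_time_h),
      high_time_h = sum(.data$high_time_h),
      overall_impulse_bwh = sum(.data$overall_impulse_bwh),
      high_impulse_bwh = sum(.data$high_impulse_bwh),
      .groups = "drop") |>
    dplyr::mutate(
      norm_overall_bw = .data$overall_impulse_bwh / .data$loading_time_h,
      norm_high_bw = .data$high_impulse_bwh / .data$loading_time_h)

  profiles <- dplyr::bind_rows(profiles)

  measures <- draw_outcomes(
    stats::setNames(gt_participants$norm_high_bw,
                    gt_participants$participant_id),
    config$outcome_targets, seed = config$seed + 999983L)
  for (m in intersect(c("age", "visa_a", "pas"), names(measures))) {
    profiles[[m]] <- measures[[m]]
  }

  out <- list(
    recordings = recordings,
    profiles = profiles,
    measures = measures,
    ground_truth = list(participants = gt_participants, days = gt_days),
    artifact_logs = dplyr::bind_rows(artifact_logs),
    config = config)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d participant(s), %d recording(s), seed %d\n",
    nrow(x$profiles), length(x$recordings), x$config$seed))
  invisible(x)
}
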