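# Shared fixtures and independent oracles. Fixtures are built in code; the
# oracles are deliberately naive (explicit loops, closed forms, stats::aov)
# so they stay independent of the vectorized implementation paths they
# check.

the_start <- as.POSIXct("2026-03-02 08:00:00", tz = "UTC")

make_recording <- function(f_heel, f_mid, f_fore, pid = "P01", sid = "S01",
                           start = the_start, fs = 20, day = 1L) {
  insole_recording(f_heel = f_heel, f_mid = f_mid, f_fore = f_fore,
                   participant_id = pid, session_id = sid,
                   start_time = start, sample_rate = fs, day_index = day)
}

make_trace <- function(load, fs = 20, pid = "P01", sid = "S01", day = 1L) {
  tendonload:::new_tendon_load_trace(
    t = (seq_along(load) - 1) / fs, load = load,
    meta = list(participant_id = pid, session_id = sid,
                start_time = the_start, sample_rate = fs, day_index = day))
}

test_profile <- function(pid = "P01", mass = 80, height = 1.75, ...) {
  participant_profile(pid, mass = mass, height = height, ...)
}

# simulated gait: raised-cosine stance pulses 0..peak N total force on the
# forefoot, zero in swing
gait_forces <- function(n_steps = 20, fs = 20, peak_n = 1500,
                        stance_s = 0.7, gap_s = 0.5) {
  period <- stance_s + gap_s
  t <- seq(0, n_steps * period, by = 1 / fs)
  phase <- t %% period
  f <- ifelse(phase < stance_s,
              peak_n / 2 * (1 - cos(2 * pi * phase / stance_s)), 0)
  f
}

# random non-negative piecewise-constant (step) load trace
random_step_trace <- function(n_segments = 12, fs = 20) {
  lens <- sample(3:30, n_segments, replace = TRUE)
  vals <- sample(c(0, runif(n_segments - 1, 0, 5)))
  make_trace(rep(vals, lens), fs = fs)
}

# --- oracles --------------------------------------------------------------

oracle_time_above <- function(load, fs, thr) {
  cnt <- 0L
  for (x in load) if (x >= thr) cnt <- cnt + 1L
  cnt / fs / 3600
}

oracle_impulse_above <- function(t, load, thr) {
  m <- ifelse(load >= thr, load, 0)
  acc <- 0
  for (i in seq_len(length(m) - 1)) {
    acc <- acc + (m[i] + m[i + 1]) / 2 * (t[i + 1] - t[i])
  }
  acc / 3600
}

oracle_mape <- function(est, ref) {
  # est: data.frame(participant_id, estimate); ref: (participant_id, reference)
  errs <- c()
  for (i in seq_len(nrow(est))) {
    r <- ref$reference[ref$participant_id == est$participant_id[i]]
    errs <- c(errs, abs(est$estimate[i] - r) / r * 100)
  }
  mean(errs)
}

oracle_icc_aov <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  d <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  unname((msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n))
}

# small, fast synthetic scenario for pipeline-level tests
tiny_scenario <- function(seed = 5, n = 2, days = c(2, 2),
                          artifacts = artifact_spec(enabled = FALSE)) {
  scenario_config(
    n_participants = n, days_range = days, seed = seed,
    walking = list(step_period_s = 1.17, stance_fraction = 0.58,
                   peak_bw = 2.8, peak_sd_bw = 0.06, minutes_per_day = 4,
                   swing_jitter = 0.3),
    standing = list(level_bw = 0.5, sway_bw = 0.12, sway_period_s = 4,
                    minutes_per_day = 3),
    rest_minutes_per_day = 2,
    exercise = list(mode = "bernoulli", prob_day = 0.5,
                    run = list(step_period_s = 0.72, stance_fraction = 0.35,
                               peak_bw = 5.0, minutes = 1.5),
                    raises = list(reps = 8, period_s = 2, duty = 0.6,
                                  peak_bw = 4.0)),
    artifacts = artifacts)
}
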