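test_that("waveform bookkeeping is exact for rectangular segments", {
  wf <- generate_load_waveform(list(tendonload:::seg_constant(36, 2)), 20)
  bk <- wf$bookkeeping
  expect_equal(bk$impulse_above_bwh, c(0.02, 0), tolerance = 1e-12)
  expect_equal(bk$time_above_h, c(36 / 3600, 0), tolerance = 1e-12)

  empty <- generate_load_waveform(list(tendonload:::seg_rest(0)), 20)
  expect_length(empty$load, 0)
  expect_equal(empty$bookkeeping$impulse_above_bwh, c(0, 0))
})

test_that("closed-form bookkeeping matches a fine-grid numerical oracle", {
  set.seed(19)
  gaps <- 0.5 * (1 + 0.3 * (runif(60) - 0.5))
  peaks <- pmin(2.95, pmax(2.65, rnorm(60, 2.8, 0.06)))
  segs <- list(
    tendonload:::seg_rest(12),
    tendonload:::seg_pulses(peaks, 0.68, gaps, lead_s = 0.3),
    tendonload:::seg_constant(60, 0.5, sway_bw = 0.12, sway_period_s = 4,
                              phase = 1.1),
    tendonload:::seg_pulses(5, 0.25, rep(0.45, 30), lead_s = 0.1))
  # oracle: rectangle sum on a 2 kHz grid of the same continuous waveform
  fine <- generate_load_waveform(segs, sample_rate = 2000)
  book <- generate_load_waveform(segs, sample_rate = 20)$bookkeeping
  for (i in 1:2) {
    thr <- book$threshold[i]
    num_time <- sum(fine$load >= thr) / 2000 / 3600
    num_imp <- sum(fine$load[fine$load >= thr]) / 2000 / 3600
    expect_lt(abs(book$time_above_h[i] / num_time - 1), 0.005)
    expect_lt(abs(book$impulse_above_bwh[i] / num_imp - 1), 0.005)
  }
})

test_that("force synthesis inverts the load estimation model", {
  prof <- test_profile()
  g <- sensor_geometry()

  const2 <- waveform_to_forces(rep(2, 100), g, prof)
  expect_equal(estimate_trace(const2, g, prof)$load, rep(2, 100),
               tolerance = 1e-12)

  zero <- waveform_to_forces(rep(0, 50), g, prof)
  expect_equal(unname(as.matrix(zero[, -1])), matrix(0, 50, 3))

  set.seed(23)
  gaps <- 0.5 * (1 + 0.3 * (runif(30) - 0.5))
  wf <- generate_load_waveform(
    list(tendonload:::seg_pulses(rnorm(30, 2.8, 0.06), 0.68, gaps),
         tendonload:::seg_constant(20, 0.5, 0.12, 4, 0.3)), 20)
  rec <- waveform_to_forces(wf$load, g, prof)
  expect_true(all(rec$f_heel >= 0 & rec$f_mid >= 0 & rec$f_fore >= 0))
  est <- estimate_trace(rec, g, prof)$load
  nz <- wf$load > 0
  expect_lt(max(abs(est[nz] / wf$load[nz] - 1)), 0.02)
})

test_that("artifact injection is seed-deterministic with identity at zero", {
  prof <- test_profile()
  rec <- waveform_to_forces(c(rep(0, 100), rep(2, 100), rep(0, 100)),
                            profile = prof)
  off <- inject_artifacts(rec, artifact_spec(enabled = FALSE), seed = 1)
  expect_equal(off$f_fore, rec$f_fore)

  zero_mag <- artifact_spec(noise_sd_n = 0, offset_prob = 1, offset_n = 0,
                            step_drift_prob = 1, step_drift_n = 0,
                            init_failure_prob = 0)
  same <- inject_artifacts(rec, zero_mag, seed = 1)
  expect_equal(same$f_heel, rec$f_heel)
  expect_equal(same$f_fore, rec$f_fore)

  a <- inject_artifacts(rec, artifact_spec(), seed = 42)
  b <- inject_artifacts(rec, artifact_spec(), seed = 42)
  expect_identical(a$f_heel, b$f_heel)
  expect_identical(attr(a, "artifact_log"), attr(b, "artifact_log"))
})

test_that("injected constant offsets are recovered by QC", {
  prof <- test_profile()
  set.seed(33)
  gaps <- 0.5 * (1 + 0.3 * (runif(50) - 0.5))
  wf <- generate_load_waveform(
    list(tendonload:::seg_rest(30),
         tendonload:::seg_pulses(rep(2.8, 50), 0.68, gaps),
         tendonload:::seg_rest(30)), 20)
  rec <- waveform_to_forces(wf$load, profile = prof)
  spec <- artifact_spec(noise_sd_n = 0, offset_prob = 1, offset_n = 50,
                        step_drift_prob = 0, init_failure_prob = 0)
  dirty <- inject_artifacts(rec, spec, seed = 3)
  res <- correct_baseline_drift(dirty)
  ep <- detect_unloaded_epochs(res$recording)
  idx <- unlist(purrr::map2(ep$i_start[ep$unloaded], ep$i_end[ep$unloaded],
                            seq))
  for (ch in c("f_heel", "f_mid", "f_fore")) {
    expect_lt(max(abs(res$recording[[ch]][idx] - rec[[ch]][idx])), 1)
  }
})

test_that("initialization failures are screened out", {
  prof <- test_profile()
  n <- 20 * 700
  rec <- waveform_to_forces(rep(0, n), profile = prof)
  spec <- artifact_spec(offset_prob = 0, step_drift_prob = 0,
                        init_failure_prob = 1)
  bad <- inject_artifacts(rec, spec, seed = 5)
  expect_true(attr(bad, "artifact_log")$init_failure)
  res <- qc_session(bad, prof)
  expect_equal(res$report$status, "excluded")
})

test_that("cohorts are deterministic given the config", {
  cfg <- tiny_scenario(seed = 13, artifacts = artifact_spec())
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$measures, b$measures)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$recordings[[3]]$f_fore, b$recordings[[3]]$f_fore)
})

test_that("ground truth is additive across days", {
  cfg <- tiny_scenario(seed = 17, days = c(3, 3))
  coh <- generate_cohort(cfg)
  days <- coh$ground_truth$days
  parts <- coh$ground_truth$participants
  agg <- days |>
    dplyr::filter(!.data$init_failure) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(lt = sum(.data$loading_time_h),
                     oi = sum(.data$overall_impulse_bwh))
  expect_equal(agg$lt, parts$loading_time_h)
  expect_equal(agg$oi, parts$overall_impulse_bwh)
  expect_true(all(parts$high_time_h <= parts$loading_time_h))
  expect_true(all(parts$high_impulse_bwh <= parts$overall_impulse_bwh))
})

test_that("a two-participant walking-only cohort is recovered end to end", {
  cfg <- scenario_config(
    n_participants = 2, days_range = c(1, 1), seed = 29,
    walking = list(step_period_s = 1.17, stance_fraction = 0.58,
                   peak_bw = 2.8, peak_sd_bw = 0.06, minutes_per_day = 5,
                   swing_jitter = 0.3),
    standing = list(level_bw = 0.5, sway_bw = 0.12, sway_period_s = 4,
                    minutes_per_day = 3),
    rest_minutes_per_day = 2,
    exercise = list(mode = "none", prob_day = 0,
                    run = list(step_period_s = 0.72, stance_fraction = 0.35,
                               peak_bw = 5, minutes = 0),
                    raises = list(reps = 0, period_s = 2, duty = 0.6,
                                  peak_bw = 4)),
    artifacts = artifact_spec(enabled = FALSE))
  coh <- generate_cohort(cfg)
  res <- process_cohort(coh$recordings, coh$profiles)
  m <- dplyr::inner_join(res$summaries, coh$ground_truth$participants,
                         by = "participant_id",
                         suffix = c("", "_gt"))
  expect_lt(max(abs(m$loading_time_h / m$loading_time_h_gt - 1)), 0.02)
  expect_lt(max(abs(m$overall_impulse_bwh / m$overall_impulse_bwh_gt - 1)),
            0.02)
  expect_equal(m$high_impulse_bwh, m$high_impulse_bwh_gt, tolerance = 1e-9)
})

test_that("a perfect outcome correlation target gives a comonotone draw", {
  set.seed(4)
  nh <- stats::setNames(rlnorm(40, -2.5, 0.5), sprintf("P%02d", 1:40))
  out <- tendonload:::draw_outcomes(nh, c(heel_raise_height = 1), seed = 2)
  expect_equal(cor(nh, out$heel_raise_height, method = "spearman"), 1)
})

test_that("invalid generator configs are rejected", {
  expect_error(scenario_config(outcome_targets = c(pas = 1.2)),
               class = "tendonload_config_error")
  expect_error(tendonload:::seg_pulses(-1, 0.5, c(0.4, 0.4)),
               class = "tendonload_domain_error")
  expect_error(artifact_spec(offset_prob = 2),
               class = "tendonload_config_error")
  expect_error(scenario_config(days_range = c(5, 4)),
               class = "tendonload_config_error")
})
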