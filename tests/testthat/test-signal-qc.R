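test_that("unloaded epochs are defined by within-epoch force range", {
  n <- 20 * 60 # 1 min at 20 Hz
  zero <- make_recording(rep(0, n), rep(0, n), rep(0, n))
  ep <- detect_unloaded_epochs(zero)
  expect_true(all(ep$unloaded))

  # a constant offset is still quiet: range, not level, decides
  offset <- make_recording(rep(800, n), rep(0, n), rep(0, n))
  expect_true(all(detect_unloaded_epochs(offset)$unloaded))

  # simulated gait oscillating 0..1500 N never reads quiet
  f <- gait_forces(n_steps = 100, peak_n = 1500)
  gait <- make_recording(rep(0, length(f)), rep(0, length(f)), f)
  expect_false(any(detect_unloaded_epochs(gait)$unloaded))

  short <- make_recording(rep(0, 30), rep(0, 30), rep(0, 30))
  expect_warning(ep1 <- detect_unloaded_epochs(short), "single epoch")
  expect_equal(nrow(ep1), 1)
})

test_that("constant offsets are removed and quiet medians return to zero", {
  f <- gait_forces(n_steps = 40)
  n <- length(f)
  pad <- rep(0, 20 * 30) # 30 s unloaded on both sides
  clean_fore <- c(pad, f, pad)
  m <- length(clean_fore)
  rec <- make_recording(rep(50, m), rep(0, m), clean_fore)

  res <- correct_baseline_drift(rec)
  expect_equal(res$report$status, "corrected")
  expect_lt(max(abs(res$recording$f_heel)), 1)
  expect_lt(max(abs(res$recording$f_fore - clean_fore)), 1)

  ep <- detect_unloaded_epochs(res$recording)
  for (i in which(ep$unloaded)) {
    idx <- ep$i_start[i]:ep$i_end[i]
    expect_lt(abs(median(tendonload::total_force(res$recording)[idx])),
              1e-6)
  }
})

test_that("a zero-offset recording passes through unchanged", {
  f <- gait_forces(n_steps = 20)
  pad <- rep(0, 20 * 30)
  fore <- c(pad, f, pad)
  rec <- make_recording(rep(0, length(fore)), rep(0, length(fore)), fore)
  res <- correct_baseline_drift(rec)
  expect_equal(res$report$status, "pass")
  expect_equal(res$recording$f_fore, rec$f_fore)
})

test_that("stepwise drift anchored on both sides is corrected", {
  pad <- rep(0, 20 * 30)
  f <- gait_forces(n_steps = 20)
  first_half <- c(pad, f, pad)
  second_half <- c(pad, f, pad) + 100 # step drift +100 N mid-recording
  rec <- make_recording(rep(0, length(first_half) * 2),
                        rep(0, length(first_half) * 2),
                        c(first_half, second_half))
  res <- correct_baseline_drift(rec)
  ep <- detect_unloaded_epochs(res$recording)
  expect_true(any(ep$unloaded))
  for (i in which(ep$unloaded)) {
    idx <- ep$i_start[i]:ep$i_end[i]
    expect_lt(abs(median(tendonload::total_force(res$recording)[idx])),
              1e-6)
  }
})

test_that("drift correction is idempotent", {
  set.seed(7)
  pad <- rep(0, 20 * 30)
  f <- gait_forces(n_steps = 30)
  fore <- c(pad, f, pad, f + 40, pad) + rnorm(3 * length(pad) + 2 * length(f),
                                              sd = 1)
  rec <- make_recording(rep(0, length(fore)), rep(0, length(fore)), fore)
  once <- correct_baseline_drift(rec)
  twice <- correct_baseline_drift(once$recording)
  expect_lt(max(abs(twice$recording$f_fore - once$recording$f_fore)), 1e-6)
})

test_that("without any quiet anchor nothing is corrected", {
  n <- 20 * 60
  rec <- make_recording(rep(0, n), rep(0, n),
                        500 + 400 * sin(seq_len(n) / 5))
  expect_warning(res <- correct_baseline_drift(rec), "no unloaded epoch")
  expect_equal(res$recording$f_fore, rec$f_fore)
  expect_equal(res$report$status, "pass")
})

test_that("screening fires on each exclusion rule and passes clean days", {
  prof <- test_profile(mass = 80) # BW ~785 N
  n <- 20 * 700 # ~12 min, above the never-unloaded minimum duration

  # (a) never unloaded: force always moving, never quiet
  wandering <- 400 + 200 * sin(seq_len(n) / 7) + rep(c(0, 150), length.out = n)
  rec_a <- make_recording(rep(0, n), rep(0, n), wandering)
  rep_a <- screen_recording(rec_a, prof)
  expect_equal(rep_a$status, "excluded")
  expect_match(rep_a$exclusion_reason, "never-unloaded")

  # (b) implausible magnitude: sustained 15xBW plateau
  f <- c(rep(0, 20 * 30), rep(15 * prof$body_weight, 20 * 30))
  rec_b <- make_recording(rep(0, length(f)), rep(0, length(f)), f)
  rep_b <- screen_recording(rec_b, prof)
  expect_equal(rep_b$status, "excluded")
  expect_match(rep_b$exclusion_reason, "implausible-magnitude")

  # (c) negative dominance, carried by the drift report
  drift_report <- tibble::tibble(status = "corrected", neg_fraction = 0.05)
  pad <- rep(0, 20 * 30)
  rec_c <- make_recording(pad, pad, pad)
  rep_c <- screen_recording(rec_c, prof, drift_report = drift_report)
  expect_equal(rep_c$status, "excluded")
  expect_match(rep_c$exclusion_reason, "negative-dominance")

  # a clean synthetic walking day passes
  f <- gait_forces(n_steps = 200)
  fore <- c(pad, f, pad)
  rec_ok <- make_recording(rep(0, length(fore)), rep(0, length(fore)), fore)
  expect_equal(screen_recording(rec_ok, prof)$status, "pass")
})

test_that("screening is deterministic given the rule set", {
  prof <- test_profile()
  f <- gait_forces(n_steps = 50)
  pad <- rep(0, 20 * 30)
  fore <- c(pad, f, pad)
  rec <- make_recording(rep(0, length(fore)), rep(0, length(fore)), fore)
  expect_identical(screen_recording(rec, prof), screen_recording(rec, prof))
})
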