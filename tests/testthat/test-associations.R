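test_that("correlation strength classification partitions [-1, 1]", {
  expect_equal(classify_strength(0.625), "strong")
  expect_equal(classify_strength(0.543), "moderate")
  expect_equal(classify_strength(0.392), "weak")
  expect_equal(classify_strength(-0.62), "strong")
  # closed lower bounds
  expect_equal(classify_strength(c(0.4, 0.6, -0.4, -0.6)),
               c("moderate", "strong", "moderate", "strong"))

  grid <- seq(-1, 1, by = 0.001)
  cls <- classify_strength(grid)
  expect_false(anyNA(cls))
  expect_setequal(unique(cls), c("weak", "moderate", "strong"))
  expect_error(classify_strength(1.2), class = "tendonload_domain_error")
})

test_that("correlation tables report r, p, strength and flags per pair", {
  set.seed(15)
  loads <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:12),
    norm_overall_bw = runif(12, 0.7, 1.3),
    norm_high_bw = runif(12, 0, 0.2))
  outcomes <- tibble::tibble(
    participant_id = loads$participant_id,
    linear = 3 * loads$norm_high_bw + 1,
    flat = rep(2, 12),
    noisy = rnorm(12))
  tab <- correlation_table(loads, outcomes)
  expect_equal(nrow(tab), 6)

  lin <- tab[tab$x_name == "norm_high_bw" & tab$y_name == "linear", ]
  expect_equal(lin$r, 1)
  expect_equal(lin$strength, "strong")
  expect_true(lin$significant)

  flat <- tab[tab$y_name == "flat", ]
  expect_true(all(is.na(flat$r)))
  expect_true(all(flat$note == "zero variance"))

  # r and p are symmetric in the two vectors
  a <- pearson(loads$norm_overall_bw, outcomes$noisy)
  b <- pearson(outcomes$noisy, loads$norm_overall_bw)
  expect_equal(a$r, b$r)
  expect_equal(a$p, b$p)

  few <- correlation_table(loads[1:2, ], outcomes[1:2, ])
  expect_true(all(few$note == "insufficient pairs"))
})

test_that("capacity measures normalize moment, power and work", {
  tr <- data.frame(t_s = seq(0, 1, by = 0.01), torque_nm = 100,
                   omega_rad_s = 0.5)
  out <- capacity_measures(tr, height = 2, weight = 500) # H*W = 1000
  expect_equal(out$peak_moment, 10)
  expect_equal(out$peak_power, 5)
  expect_equal(out$work, 5, tolerance = 1e-9)

  zero <- data.frame(t_s = seq(0, 1, by = 0.01), torque_nm = 0,
                     omega_rad_s = 0.5)
  out0 <- capacity_measures(zero, 2, 500)
  expect_equal(unlist(out0), c(peak_moment = 0, peak_power = 0, work = 0))

  # triangular torque pulse: work equals the closed-form triangle area
  tt <- seq(0, 2, by = 0.001)
  torque <- ifelse(tt <= 1, 80 * tt, 80 * (2 - tt))
  tri <- data.frame(t_s = tt, torque_nm = torque, omega_rad_s = 1)
  out_tri <- capacity_measures(tri, height = 1.8, weight = 800)
  expect_equal(out_tri$work, 80 / (1.8 * 800) * 100, tolerance = 1e-9)

  # repetitions are averaged
  reps <- rbind(cbind(tr, rep = 1),
                cbind(transform(tr, torque_nm = 200), rep = 2))
  out_r <- capacity_measures(reps, 2, 500)
  expect_equal(out_r$peak_moment, 15)

  expect_error(capacity_measures(tr, height = 0, weight = 500),
               class = "tendonload_domain_error")
})

test_that("height normalization is a simple reversible percentage", {
  expect_equal(normalize_height(0.10, 1.72), 5.813953, tolerance = 1e-6)
  expect_equal(normalize_height(0, 1.72), 0)
  x <- 0.137
  expect_equal(normalize_height(x, 1.72) / 100 * 1.72, x, tolerance = 1e-12)
  expect_error(normalize_height(0.1, 0), class = "tendonload_domain_error")
})

test_that("copula-drawn outcomes land near their target correlations", {
  set.seed(50)
  # moderately skewed marginal, comparable to the cohort generator's
  # distribution of normalized high-level load
  norm_high <- stats::setNames(rlnorm(200, -2.5, 0.35),
                               sprintf("P%03d", 1:200))
  targets <- c(heel_raise_height = 0.6, age = -0.33, pas = 0.62)
  out <- tendonload:::draw_outcomes(norm_high, targets, seed = 77)
  expect_lt(abs(cor(norm_high, out$heel_raise_height) - 0.6), 0.1)
  expect_lt(abs(cor(norm_high, out$age) - (-0.33)), 0.1)
  expect_lt(abs(cor(norm_high, out$pas) - 0.62), 0.1)

  # empirical strength class agrees with the target class for most seeds
  hits <- 0
  for (s in 1:30) {
    o <- tendonload:::draw_outcomes(norm_high,
                                    c(heel_raise_height = 0.75), seed = s)
    r <- cor(norm_high, o$heel_raise_height)
    hits <- hits + (classify_strength(r) == "strong")
  }
  expect_gte(hits / 30, 0.95)
})
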