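test_that("day subsets enumerate all combinations of the first six days", {
  expect_length(enumerate_subsets(1:6, 6), 1)
  loo <- enumerate_subsets(1:6, 5)
  expect_length(loo, 6)
  omitted <- vapply(loo, function(s) setdiff(1:6, s), 0L)
  expect_setequal(omitted, 1:6)
  singles <- enumerate_subsets(1:6, 1)
  expect_equal(unlist(singles), 1:6)
  expect_length(enumerate_subsets(1:6, 3), 20)

  # only the first six recorded days are eligible
  expect_false(any(vapply(enumerate_subsets(1:9, 2),
                          function(s) any(s > 6), TRUE)))
  expect_error(enumerate_subsets(1:5, 2), class = "tendonload_domain_error")
  expect_error(enumerate_subsets(1:6, 7), class = "tendonload_domain_error")
})

test_that("MAPE matches its definition and handles zero references", {
  est <- tibble::tibble(participant_id = c("a", "b"), estimate = c(1, 2))
  ref <- tibble::tibble(participant_id = c("a", "b"), reference = c(1, 2))
  expect_equal(mape(est, ref), 0)

  est1 <- tibble::tibble(participant_id = "a", estimate = 1.1)
  ref1 <- tibble::tibble(participant_id = "a", reference = 1.0)
  expect_equal(mape(est1, ref1), 10)

  set.seed(31)
  est_r <- tibble::tibble(
    participant_id = rep(letters[1:8], each = 5),
    estimate = runif(40, 0.5, 2))
  ref_r <- tibble::tibble(participant_id = letters[1:8],
                          reference = runif(8, 0.5, 2))
  expect_lt(abs(mape(est_r, ref_r) - oracle_mape(est_r, ref_r)), 1e-12)

  ref0 <- tibble::tibble(participant_id = c("a", "b"),
                         reference = c(0, 2))
  est0 <- tibble::tibble(participant_id = c("a", "b"),
                         estimate = c(5, 3))
  expect_warning(m0 <- mape(est0, ref0), "zero reference")
  expect_equal(m0, 50)
})

test_that("Pearson wrapper matches the textbook formula", {
  x <- c(1.2, 2.5, 3.1, 4.8, 5.0)
  y <- c(0.9, 2.2, 2.8, 5.1, 4.7)
  pr <- pearson(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r_manual * sqrt(3 / (1 - r_manual^2))
  p_manual <- 2 * stats::pt(-abs(tstat), df = 3)
  expect_lt(abs(pr$r - r_manual), 1e-12)
  expect_lt(abs(pr$p - p_manual), 1e-12)

  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_warning(pr0 <- pearson(x, rep(1, 5)), "undefined")
  expect_true(is.na(pr0$r))
})

test_that("ICC(2,1) agrees with an ANOVA mean-squares oracle", {
  expect_equal(icc(cbind(1:5, 1:5, 1:5)), 1)

  m3 <- matrix(c(9, 6, 8, 2, 1, 3, 5, 7, 4), nrow = 3)
  expect_lt(abs(icc(m3) - oracle_icc_aov(m3)), 1e-9)

  set.seed(77)
  for (i in 1:10) {
    m <- matrix(rnorm(20, mean = 5), nrow = 5, ncol = 4)
    expect_lt(abs(icc(m) - oracle_icc_aov(m)), 1e-9)
  }

  # independent noise columns carry no subject signal
  set.seed(41)
  noise <- matrix(rnorm(500 * 4), nrow = 500)
  expect_lt(abs(icc(noise)), 0.15)

  expect_warning(icc(rbind(c(1, NA), c(2, 3), c(4, 5), c(1, 2))), "missing")
})

make_daily <- function(n_participants, n_days, base_overall = 1,
                       day_noise = 0.02, high_days = NULL, seed = 1) {
  # synthetic per-day metric table with controllable day-to-day structure;
  # high-level load confined to `high_days` (per participant) if given
  set.seed(seed)
  purrr::map(seq_len(n_participants), function(i) {
    lt <- 2 * (1 + day_noise * rnorm(n_days))
    ov <- base_overall * lt * (1 + day_noise * rnorm(n_days))
    hi <- rep(0, n_days)
    ht <- rep(0, n_days)
    hd <- if (is.null(high_days)) seq_len(n_days) else high_days[[i]]
    hi[hd] <- 0.2 * (1 + day_noise * rnorm(length(hd)))
    ht[hd] <- 0.05
    tibble::tibble(
      participant_id = sprintf("P%02d", i), day_index = seq_len(n_days),
      loading_time_h = lt, high_time_h = ht,
      overall_impulse_bwh = ov, high_impulse_bwh = hi)
  }) |> dplyr::bind_rows()
}

test_that("a stationary cohort yields small, shrinking subsampling error", {
  daily <- make_daily(10, 8, day_noise = 0.05, seed = 3)
  rep <- reliability_analysis(daily)
  ov <- rep[rep$metric == "overall", ]
  expect_true(all(diff(ov$mape_mean) <= 0))
  expect_lt(ov$mape_mean[ov$k == 6], 3)
  expect_equal(rep$n_subsets, rep(choose(6, 1:6), each = 2))
})

test_that("exercise on one of six days inflates single-day high-level error", {
  set.seed(9)
  high_days <- lapply(1:10, function(i) sample(1:6, 1))
  daily <- make_daily(10, 6, high_days = high_days, seed = 4)
  rep <- reliability_analysis(daily)
  k1 <- rep[rep$k == 1, ]
  expect_gt(k1$mape_mean[k1$metric == "high"],
            3 * k1$mape_mean[k1$metric == "overall"])
  # with exactly six recorded days the 6-day subset is the reference
  k6 <- rep[rep$k == 6, ]
  expect_equal(k6$mape_mean, c(0, 0), tolerance = 1e-12)
})

test_that("subset means of raw loading time average to k/6 of the total", {
  daily <- make_daily(4, 6, day_noise = 0.2, seed = 12)
  for (k in c(1, 2, 5)) {
    est <- tendonload:::subset_estimates(daily,
                                         unique(daily$participant_id), k)
    per_part <- tapply(est$loading_time_h, est$participant_id, mean)
    total <- tapply(daily$loading_time_h, daily$participant_id, sum)
    expect_equal(unname(per_part[names(total)]), unname(total) * k / 6)
  }
})

test_that("agreement statistics are invariant to affine rescaling", {
  daily <- make_daily(8, 6, day_noise = 0.1, seed = 6)
  rep1 <- reliability_analysis(daily, k = c(1, 3))
  scaled <- dplyr::mutate(
    daily,
    overall_impulse_bwh = 3 * .data$overall_impulse_bwh,
    high_impulse_bwh = 3 * .data$high_impulse_bwh)
  rep2 <- reliability_analysis(scaled, k = c(1, 3))
  expect_equal(rep2$pearson_r, rep1$pearson_r, tolerance = 1e-12)
  expect_equal(rep2$mape_mean, rep1$mape_mean, tolerance = 1e-12)
  expect_equal(rep2$icc, rep1$icc, tolerance = 1e-9)
})

test_that("participants with fewer than six days are excluded with warning", {
  daily <- make_daily(5, 6, seed = 8)
  short <- make_daily(1, 4, seed = 9) |>
    dplyr::mutate(participant_id = "P99")
  expect_warning(rep <- reliability_analysis(dplyr::bind_rows(daily, short),
                                             k = 1),
                 "fewer than 6")
  expect_equal(rep$n_participants[1], 5)
})
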