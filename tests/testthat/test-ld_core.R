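# Luria-Delbruck pmf, MSS MLE and Drake median estimators.

test_that("MSS pmf matches closed forms and the brute-force recursion", {
  expect_identical(mss_pmf(0, 0), 1)
  expect_equal(mss_pmf(1, 0), exp(-1), tolerance = 1e-15)
  p <- mss_pmf(1, 2)
  expect_equal(p[2], exp(-1) / 2, tolerance = 1e-15)          # p1 = m p0 / 2
  expect_equal(p[3], exp(-1) * (1 / 6 + 1 / 8), tolerance = 1e-14)
  for (m in c(0.1, 1, 5)) {
    expect_equal(mss_pmf(m, 50), oracle_ld_pmf(m, 50), tolerance = 1e-12)
  }
  expect_error(mss_pmf(-0.1, 5), "nonnegative")
  expect_error(mss_pmf(1, -1))
})

test_that("MSS pmf entries are probabilities whose partial sums approach 1", {
  for (m in c(0.5, 2, 20, 50)) {
    p <- mss_pmf(m, 500)
    expect_true(all(p >= 0))
    expect_lte(sum(p), 1 + 1e-12)
  }
  # heavy ~m/r tail: most of the mass is below a few thousand mutants
  expect_gt(sum(mss_pmf(2, 4000)), 0.999)
})

test_that("MSS MLE agrees with a fine grid-search oracle", {
  r <- c(0, 0, 1, 0, 2, 0, 0, 1, 0, 0)
  a <- fluctuation_assay("g", "CAN1", r, N_t = 1e8)
  grid <- seq(0.001, 10, by = 0.001)
  ll <- vapply(grid, function(m) {
    pm <- oracle_ld_pmf(m, max(r))
    sum(log(pm[r + 1]))
  }, numeric(1))
  m_grid <- grid[which.max(ll)]
  est <- mss_mle(a)
  expect_lt(abs(est$m - m_grid), 0.002)  # within one oracle grid step
  expect_equal(est$rate, est$m / 1e8)
  expect_false(est$is_upper_bound)
})

test_that("MSS MLE recovers the simulated m and reports a sane CI", {
  a <- sample_ld_counts(1000, m = 2, N_t = 1e8, seed = 11)
  est <- mss_mle(a)
  expect_lt(abs(est$m - 2) / 2, 0.10)
  expect_lt(est$ci_low, est$rate)
  expect_gt(est$ci_high, est$rate)
})

test_that("all-zero assays give the closed-form zero-class upper bound", {
  a <- fluctuation_assay("quiet", "GCR", rep(0L, 10), N_t = 1e9)
  est <- mss_mle(a)
  expect_true(est$is_upper_bound)
  # P(all C cultures mutant-free) = exp(-m C) = 0.05  =>  m = ln(20)/C
  expect_equal(est$m, log(20) / 10, tolerance = 1e-12)
  expect_equal(est$rate, log(20) / 10 / 1e9, tolerance = 1e-12)
})

test_that("plating-fraction correction scales counts before estimation", {
  a_full <- fluctuation_assay("g", "CAN1", c(2, 4, 6, 8, 10, 12), N_t = 1e8)
  a_half <- fluctuation_assay("g", "CAN1", c(1, 2, 3, 4, 5, 6), N_t = 1e8,
                              plated_fraction_selective = 0.5)
  expect_equal(mss_mle(a_half)$m, mss_mle(a_full)$m, tolerance = 1e-6)
  expect_equal(drake_median_rate(a_half)$rate, drake_median_rate(a_full)$rate)
})

test_that("Drake estimator solves mu ln(N mu) = f to oracle precision", {
  for (case in list(c(20, 2e8), c(7, 5e7), c(100, 1e9))) {
    mu <- as.numeric(drake_rate(case[1], case[2]))
    expect_lt(abs(mu - oracle_drake(case[1], case[2])) / mu, 1e-12)
    # the defining relation itself
    f <- case[1] / case[2]
    expect_lt(abs(mu * log(case[2] * mu) - f) / f, 1e-12)
  }
  z <- drake_rate(0, 1e8)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "below_detection"))
  expect_error(drake_rate(NA, 1e8))
  expect_error(drake_rate(-1, 1e8))
  expect_error(drake_rate(1, 0))
})

test_that("Drake rate is strictly increasing in r and the low-count root exceeds f", {
  mus <- as.numeric(drake_rate(1:50, 2e8))
  expect_true(all(diff(mus) > 0))
  # with r < e mutants, ln(N mu) < 1 at the root, so mu > f
  expect_gt(as.numeric(drake_rate(1, 1e8)), 1 / 1e8)
  # scaling (r, N) -> (2r, 2N) keeps f but enters through ln(N mu)
  mu1 <- as.numeric(drake_rate(20, 2e8))
  mu2 <- as.numeric(drake_rate(40, 4e8))
  expect_lt(mu2, mu1)
  expect_lt(abs(mu2 * log(4e8 * mu2) - 1e-7) / 1e-7, 1e-12)
})

test_that("median CI uses exact binomial order statistics", {
  res5 <- median_rate_with_ci(c(1, 2, 3, 4, 5))
  expect_equal(res5$median, 3)
  expect_false(res5$ci_available)

  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9)  # n = 15
  res <- median_rate_with_ci(x)
  # enumerate the binomial tail: largest k with sum_{j<k} C(15,j)/2^15 <= 0.025
  tails <- cumsum(choose(15, 0:15) / 2^15)
  k <- max(which(tails <= 0.025))       # tails[k] = P(X <= k-1)
  expect_identical(res$k_low, k)
  expect_identical(res$k_high, 15L - k + 1L)
  expect_identical(c(res$k_low, res$k_high), c(4L, 12L))
  s <- sort(x)
  expect_equal(res$ci_low, s[4])
  expect_equal(res$ci_high, s[12])

  same <- median_rate_with_ci(rep(2.5, 9))
  expect_equal(same$median, 2.5)
  expect_equal(same$ci_low, 2.5)
  expect_equal(same$ci_high, 2.5)
  expect_error(median_rate_with_ci(numeric(0)), "empty")
})

test_that("median CI is permutation invariant", {
  set.seed(5)
  x <- rexp(13)
  ref <- median_rate_with_ci(x)
  for (i in 1:5) expect_identical(median_rate_with_ci(sample(x)), ref)
})

test_that("Drake median estimate recovers a simulated rate and flags zero medians", {
  a <- sample_ld_counts(15, m = 4, N_t = 1e8, seed = 21)
  est <- drake_median_rate(a)
  # the Drake median is a rough estimator; demand the right order of magnitude
  expect_gt(est$rate, 4e-8 / 3)
  expect_lt(est$rate, 4e-8 * 3)
  expect_true(est$ci_low <= est$rate && est$rate <= est$ci_high)

  quiet <- fluctuation_assay("quiet", "his7-2", c(0, 0, 0, 1, 0, 0, 0, 0, 1, 0),
                             N_t = 2e8)
  b <- drake_median_rate(quiet)
  expect_true(b$is_upper_bound)
  expect_equal(b$rate, as.numeric(drake_rate(1, 2e8)))  # r = 1 detection limit
})

test_that("pooled-frequency Drake variant is exposed and differs in general", {
  a <- sample_ld_counts(15, m = 4, N_t = 1e8, seed = 22)
  per <- drake_median_rate(a, per_culture = TRUE)
  pooled <- drake_median_rate(a, per_culture = FALSE)
  expect_false(pooled$ci_available)
  expect_gt(pooled$rate, 0)
})
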