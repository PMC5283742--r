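test_that("pooled standardized difference matches the hand formula", {
  a <- fixed_moments(10, 10, 2, seed = 1)
  b <- fixed_moments(10, 12, 2, seed = 2)
  ef <- cohen_d_pooled(a, b)
  expect_equal(ef$d, 1.0, tolerance = 1e-12)
  expect_equal(ef$magnitude, "moderate")
  se_hand <- sqrt(1 / 10 + 1 / 10 + 1 / (2 * 20))
  expect_equal(ef$se, se_hand, tolerance = 1e-12)
  expect_equal(ef$lower, 1 - qnorm(0.95) * se_hand, tolerance = 1e-12)

  same <- cohen_d_pooled(a, a)
  expect_equal(same$d, 0)
  expect_equal(same$magnitude, "trivial")

  expect_error(cohen_d_pooled(rep(1, 5), rep(2, 5)), "zero pooled variance")
  expect_error(cohen_d_pooled(1, c(1, 2)), "n >= 2")
})

test_that("standardized difference is antisymmetric in the groups", {
  set.seed(3)
  a <- rnorm(8, 5, 1); b <- rnorm(12, 6, 2)
  expect_equal(cohen_d_pooled(a, b)$d, -cohen_d_pooled(b, a)$d)
})

test_that("percent difference works on the log scale with a t oracle", {
  a <- c(10, 12, 14)
  expect_equal(percent_difference(a, 1.2 * a)$pct, 20, tolerance = 1e-9)
  expect_equal(percent_difference(a, a)$pct, 0)

  b <- c(13, 15, 18)
  got <- percent_difference(a, b)
  tt <- t.test(log(b), log(a), var.equal = TRUE, conf.level = 0.90)
  expect_equal(got$pct,
               unname(100 * (exp(tt$estimate[1] - tt$estimate[2]) - 1)),
               tolerance = 1e-9)
  expect_equal(got$lower, 100 * (exp(tt$conf.int[1]) - 1), tolerance = 1e-9)
  expect_equal(got$upper, 100 * (exp(tt$conf.int[2]) - 1), tolerance = 1e-9)

  expect_error(percent_difference(c(0, 1, 2), a), "raw")
})

test_that("percent difference inverts as a ratio when groups swap", {
  set.seed(4)
  a <- exp(rnorm(6)); b <- exp(rnorm(6, 0.3))
  p_ab <- percent_difference(a, b)$pct
  p_ba <- percent_difference(b, a)$pct
  expect_equal((1 + p_ab / 100) * (1 + p_ba / 100), 1, tolerance = 1e-9)
})

test_that("MBI labels follow the probability bands and the unclear rule", {
  # clearly positive effect: d = 1.0, CI excludes -swd
  m <- mbi_label(1.0, 0.5, 1.5, swd = 0.2)
  expect_equal(m$direction, "positive")
  expect_gt(m$probabilities["positive"], 0.95)
  expect_true(m$label %in% c("very likely", "most likely"))

  # interval spanning both substantial signs is unclear
  m <- mbi_label(0.05, -0.4, 0.5, swd = 0.2)
  expect_equal(m$label, "unclear")

  # 80% chance of a substantial positive effect -> likely
  se <- (0.2 - 0.5) / qnorm(0.2)
  z <- qnorm(0.95)
  m <- mbi_label(0.5, 0.5 - z * se, 0.5 + z * se, swd = 0.2)
  expect_equal(unname(round(100 * m$probabilities["positive"])), 80)
  expect_equal(m$label, "likely")

  expect_error(mbi_label(1, 0.5, 1.5, swd = 0), "swd")
})

test_that("MBI probabilities always sum to one", {
  set.seed(12)
  for (i in 1:20) {
    est <- rnorm(1)
    se <- runif(1, 0.05, 1)
    z <- qnorm(0.95)
    m <- mbi_label(est, est - z * se, est + z * se,
                   swd = runif(1, 0.05, 0.5),
                   df = sample(c(Inf, 5, 30), 1))
    expect_equal(unname(sum(m$probabilities)), 1, tolerance = 1e-9)
  }
})

test_that("magnitude scales reproduce the printed thresholds at boundaries", {
  expect_equal(magnitude_d(c(0.1, 0.2, 0.21, 0.6, 0.61, 1.0, 1.2, 1.21, 2.0, 2.01)),
               c("trivial", "trivial", "small", "small", "moderate",
                 "moderate", "moderate", "large", "large", "very large"))
  expect_equal(magnitude_d(-1.0), "moderate")
  expect_equal(magnitude_r(c(0.1, 0.11, 0.3, 0.31, 0.44, 0.5, 0.51, 0.7,
                             0.71, 0.9, 0.91)),
               c("trivial", "small", "small", "moderate", "moderate",
                 "moderate", "large", "large", "very large", "very large",
                 "almost perfect"))
})

test_that("Fisher-z interval matches the hand computation and shrinks with n", {
  pr <- pair_with_correlation(90, -0.44, seed = 2)
  got <- pearson_ci(pr$x, pr$y)
  expect_equal(got$r, -0.44, tolerance = 1e-12)
  z_hand <- atanh(-0.44)
  half <- qnorm(0.95) / sqrt(90 - 3)
  expect_equal(got$lower, tanh(z_hand - half), tolerance = 1e-12)
  expect_equal(got$upper, tanh(z_hand + half), tolerance = 1e-12)
  expect_equal(got$magnitude, "moderate")
  expect_equal(got$clarity, "clear")

  wide <- pearson_ci(pair_with_correlation(20, -0.44, seed = 3)$x,
                     pair_with_correlation(20, -0.44, seed = 3)$y)
  expect_gt(wide$upper - wide$lower, got$upper - got$lower)

  lin <- pearson_ci(1:10, 2 * (1:10))
  expect_equal(lin$r, 1)
  expect_equal(c(lin$lower, lin$upper), c(1, 1))

  expect_error(pearson_ci(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_ci(1:3, 1:3), "4 complete pairs")
})

test_that("efficacy follows the goals-per-shot formula with validation", {
  expect_equal(efficacy(0, 5), 0)
  expect_equal(efficacy(1, 3), 33.3)
  expect_equal(efficacy(4, 4), 100)
  expect_error(efficacy(1, 0), "shots")
  expect_error(efficacy(5, 3), "goals")
})
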