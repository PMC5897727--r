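test_that("angular binning partitions [0, 90] and keeps the total count", {
  d <- angular_distribution(c(0, 7, 15, 44.9, 45, 89, 90))
  expect_equal(sum(d$counts), 7)
  expect_equal(d$bin_edges, seq(0, 90, by = 15))
  expect_error(angular_distribution(c(-3, 10)), "folded")
})

test_that("chi-square vs random: zero on uniform counts, hand-computed
           concentrated fixture, bin-permutation invariance", {
  r <- chi_square_vs_random(rep(10, 6))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_warning(r2 <- chi_square_vs_random(c(10, 0, 0, 0, 0, 0)),
                 "below 5")
  expect_equal(r2$chi2, 50)                        # sum (O-E)^2/E, E = 10/6
  expect_equal(r2$df, 5L)
  expect_warning(r3 <- chi_square_vs_random(c(0, 0, 10, 0, 0, 0)), "below 5")
  expect_equal(r3$chi2, r2$chi2)                   # permutation invariant
  # merging variant collapses bins until expectations reach 5
  expect_silent(r4 <- chi_square_vs_random(c(10, 0, 0, 0, 0, 0),
                                           merge_bins = TRUE))
  expect_true(all(r4$expected >= 5))
})

test_that("chi-square type-I error is close to nominal on uniform angular
           samples", {
  set.seed(101)
  rej <- mean(replicate(2000, {
    d <- angular_distribution(stats::runif(100, 0, 90))
    chi_square_vs_random(d)$p < 0.05
  }))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("between-group chi-square: identical distributions, 2x2 hand
           value, null p-values uniform", {
  expect_equal(chi_square_between_groups(c(5, 5), c(10, 10))$chi2, 0)
  r <- chi_square_between_groups(c(10, 20), c(20, 10))
  expect_equal(r$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(r$df, 1L)
  set.seed(7)
  ps <- replicate(400, {
    a <- angular_distribution(stats::runif(80, 0, 90))
    b <- angular_distribution(stats::runif(80, 0, 90))
    chi_square_between_groups(a, b)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("one-sample t: exact null, hand-computed fixture, type-I
           calibration", {
  r0 <- one_sample_t(rep(1, 5), 1)
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)
  r <- one_sample_t(c(1.2, 1.4, 1.6), 1)
  expect_equal(r$t, 0.4 / (0.2 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  set.seed(5)
  rej <- mean(replicate(2000, one_sample_t(stats::rnorm(9, 1, 0.1))$p < 0.05))
  expect_gt(rej, 0.035); expect_lt(rej, 0.065)
})

test_that("two-sample t: identical samples, pooled hand value, auto rule
           calibration, group relabelling symmetry", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6), "pooled")
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4L)
  ra <- two_sample_t(c(1, 2, 3, 2), c(4, 6, 5, 7))
  rb <- two_sample_t(c(4, 6, 5, 7), c(1, 2, 3, 2))
  expect_equal(ra$p, rb$p)
  expect_equal(ra$t, -rb$t)
  set.seed(6)
  rej <- mean(replicate(2000,
    two_sample_t(stats::rnorm(10), stats::rnorm(10))$p < 0.05))
  expect_gt(rej, 0.035); expect_lt(rej, 0.065)
})

test_that("paired t: equal inputs, zero-variance guard, hand-computed
           fixture", {
  expect_equal(paired_t(c(3, 4, 5), c(3, 4, 5))$p, 1)
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "degenerate")
  d <- c(2, 1, 3, 2, 2, 2)
  r <- paired_t(d, rep(0, 6))
  expect_equal(r$t, 2 / (stats::sd(d) / sqrt(6)), tolerance = 1e-12)
  expect_equal(r$df, 5L)
})

test_that("one-way ANOVA: degenerate guard, hand-computed F, Bonferroni
           capping, type-I calibration", {
  g0 <- anova_oneway(list(rep(2, 4), rep(2, 4)))
  expect_true(g0$degenerate); expect_equal(g0$F, 0); expect_equal(g0$p, 1)
  r <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(r$F, 3)
  expect_equal(c(r$df1, r$df2), c(2, 6))
  expect_true(all(r$pairwise <= 1, na.rm = TRUE))
  set.seed(9)
  rej <- mean(replicate(2000, {
    anova_oneway(list(stats::rnorm(10), stats::rnorm(10),
                      stats::rnorm(10)))$p < 0.05
  }))
  expect_gt(rej, 0.035); expect_lt(rej, 0.065)
})

test_that("regression slope machinery: perfect fits flagged, opposite slopes
           detected, identical groups null", {
  x <- 1:6
  r0 <- regression_slope_tests(x, 2 * x, x, 2 * x)
  expect_true(r0$degenerate)
  expect_equal(r0$group_a$slope, 2)
  set.seed(2)
  ya <- x + stats::rnorm(6, 0, 0.05)
  yb <- -x + stats::rnorm(6, 0, 0.05)
  r <- regression_slope_tests(x, ya, x, yb)
  expect_lt(r$p_slopes_equal, 0.001)
  expect_lt(r$group_a$p_slope_zero, 0.001)
  y <- x + stats::rnorm(6, 0, 0.3)
  ri <- regression_slope_tests(x, y, x, y)
  expect_equal(ri$F, 0, tolerance = 1e-9)
  expect_gt(ri$p_slopes_equal, 0.99)
  expect_error(regression_slope_tests(rep(1, 4), 1:4, x[1:4], 1:4), "rank")
  # the comparison F equals the anova() of nested common/separate-slope fits
  g <- factor(rep(c("a", "b"), each = 6))
  m0 <- stats::lm(c(ya, yb) ~ g + rep(x, 2))
  m1 <- stats::lm(c(ya, yb) ~ g * rep(x, 2))
  expect_equal(r$F, stats::anova(m0, m1)$F[2], tolerance = 1e-9)
})

test_that("confidence band: narrowest at mean x, contains the fit, nominal
           coverage", {
  set.seed(3)
  x <- seq(0, 10, length.out = 25)
  y <- 2 + 0.5 * x + stats::rnorm(25)
  cb <- confidence_band(x, y)
  width <- cb$upr - cb$lwr
  expect_equal(which.min(width), which.min(abs(x - mean(x))))
  expect_true(all(cb$lwr <= cb$fit & cb$fit <= cb$upr))
  covered <- replicate(2000, {
    yy <- 2 + 0.5 * x + stats::rnorm(25)
    b <- confidence_band(x, yy, at = mean(x))
    b$lwr <= 2 + 0.5 * mean(x) && 2 + 0.5 * mean(x) <= b$upr
  })
  expect_equal(mean(covered), 0.95, tolerance = 0.02)
})

test_that("statistical power matches the embryo-cohort design: 9 vs 9
           embryos with a 0.3 score difference", {
  set.seed(12)
  rej <- mean(replicate(500, {
    two_sample_t(stats::rnorm(9, 1.3, 0.15), stats::rnorm(9, 1.0, 0.15))$p <
      0.01
  }))
  expect_gte(rej, 0.8)
})

test_that("p-values stay within [0, 1] across assorted inputs", {
  set.seed(31)
  for (i in 1:25) {
    a <- stats::rnorm(sample(3:12, 1)); b <- stats::rnorm(sample(3:12, 1))
    expect_true(two_sample_t(a, b)$p >= 0 && two_sample_t(a, b)$p <= 1)
    d <- angular_distribution(stats::runif(40, 0, 90))
    expect_true(chi_square_vs_random(d)$p >= 0)
  }
})
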