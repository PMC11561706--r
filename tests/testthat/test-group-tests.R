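test_that("z-test matches the normal closed form", {
  same <- z_test_two_predictions(list(mu = 5, variance = 2),
                                 list(mu = 5, variance = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  zt <- z_test_two_predictions(list(mu = 0, variance = 1),
                               list(mu = 2, variance = 1))
  expect_equal(zt$statistic, sqrt(2), tolerance = 1e-5)
  expect_equal(zt$p_value, 0.15730, tolerance = 1e-4)
  expect_equal(zt$effect, 2)

  # antisymmetric under group swap
  rev <- z_test_two_predictions(list(mu = 2, variance = 1),
                                list(mu = 0, variance = 1))
  expect_equal(rev$effect, -zt$effect)
  expect_equal(rev$p_value, zt$p_value)

  deg <- z_test_two_predictions(list(mu = 0, variance = 0),
                                list(mu = 1, variance = 0))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)
})

test_that("meta-regression reduces to the z-test with one observation per group", {
  a <- data.frame(mu = 3.1, variance = 0.8)
  b <- data.frame(mu = 5.4, variance = 1.7)
  expect_warning(meta <- meta_regression_groups(a, b), "z-test")
  zt <- z_test_two_predictions(a, b)
  expect_equal(meta$effect, zt$effect, tolerance = 1e-10)
  expect_equal(meta$se, zt$se, tolerance = 1e-10)
  expect_equal(meta$p_value, zt$p_value, tolerance = 1e-10)
})

test_that("with equal variances and tau2 pinned at zero the meta-regression is the pooled z-test", {
  set.seed(81)
  a <- data.frame(mu = rnorm(8, 50, 3), variance = rep(4, 8))
  b <- data.frame(mu = rnorm(12, 53, 3), variance = rep(4, 12))
  meta <- meta_regression_groups(a, b, tau2 = 0)
  pooled_se <- sqrt(4 / 8 + 4 / 12)
  expect_equal(meta$effect, mean(b$mu) - mean(a$mu), tolerance = 1e-8)
  expect_equal(meta$se, pooled_se, tolerance = 1e-8)
  expect_equal(meta$statistic, (mean(b$mu) - mean(a$mu)) / pooled_se,
               tolerance = 1e-8)
  expect_equal(meta$tau2, 0)
})

test_that("identical groups give a zero effect and effects are antisymmetric", {
  g <- data.frame(mu = c(10, 11, 12), variance = c(1, 1.5, 2))
  same <- meta_regression_groups(g, g)
  expect_equal(same$effect, 0, tolerance = 1e-10)

  set.seed(82)
  a <- data.frame(mu = rnorm(6, 40, 2), variance = runif(6, 0.5, 2))
  b <- data.frame(mu = rnorm(6, 44, 2), variance = runif(6, 0.5, 2))
  ab <- meta_regression_groups(a, b)
  ba <- meta_regression_groups(b, a)
  expect_equal(ab$effect, -ba$effect, tolerance = 1e-8)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-8)
  expect_gte(ab$tau2, 0)
})

test_that("REML estimates agree with the metafor reference implementation", {
  set.seed(83)
  for (i in 1:5) {
    a <- data.frame(mu = rnorm(9, 30, 4), variance = runif(9, 0.5, 3))
    b <- data.frame(mu = rnorm(11, 33, 4), variance = runif(11, 0.5, 3))
    ours <- meta_regression_groups(a, b)
    ref <- metafor::rma(yi = c(a$mu, b$mu), vi = c(a$variance, b$variance),
                        mods = ~ c(rep(0, 9), rep(1, 11)),
                        method = "REML", test = "z")
    expect_equal(ours$effect, unname(ref$beta[2, 1]), tolerance = 1e-5)
    expect_equal(ours$se, ref$se[2], tolerance = 1e-5)
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-4)
    expect_equal(ours$p_value, ref$pval[2], tolerance = 1e-4)
  }
})

test_that("meta-regression detects a three-sigma group difference", {
  set.seed(84)
  hits <- vapply(1:200, function(i) {
    a <- data.frame(mu = rnorm(10, 0, 1), variance = rep(1, 10))
    b <- data.frame(mu = rnorm(10, 3, 1), variance = rep(1, 10))
    meta_regression_groups(a, b)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("aggregate mode collapses groups to their mean prediction", {
  a <- data.frame(mu = c(10, 12), variance = c(2, 2))
  b <- data.frame(mu = c(20, 22), variance = c(2, 2))
  expect_warning(agg <- meta_regression_groups(a, b, aggregate = TRUE),
                 "z-test")
  expect_equal(agg$effect, 10)
  expect_equal(agg$se, sqrt(1 + 1))  # var of each mean = 2/2
})

test_that("Mann-Whitney matches enumeration and is rank-invariant", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, mww_exact_oracle(c(1, 2, 3), c(4, 5, 6)))

  scaled <- mann_whitney(c(1, 2, 3) * 7, c(4, 5, 6) * 7)
  expect_equal(scaled$statistic, res$statistic)
  expect_equal(scaled$p_value, res$p_value)

  set.seed(85)
  for (i in 1:10) {
    a <- round(runif(sample(3:6, 1)), 4)
    b <- round(runif(sample(3:6, 1)), 4)
    if (length(intersect(a, b)) > 0) next
    expect_equal(mann_whitney(a, b)$p_value, mww_exact_oracle(a, b),
                 tolerance = 1e-12)
  }

  ident <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_gte(ident$p_value, 0.99)
})
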