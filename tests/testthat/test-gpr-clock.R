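test_that("RBF kernel evaluates its closed form and is symmetric", {
  p <- kernel_params(1, 1, 1)
  expect_equal(rbf_kernel(c(0, 0), c(0, 0), p)[1, 1], 1)       # zero distance
  expect_equal(rbf_kernel(0, 1, p)[1, 1], exp(-0.5))           # unit distance
  p2 <- kernel_params(4, 2, 1)
  expect_equal(rbf_kernel(0, 3, p2)[1, 1], 4 * exp(-9 / 8))

  set.seed(71)
  X <- matrix(rnorm(12), 4, 3)
  K <- rbf_kernel(X, NULL, p)
  expect_equal(K, t(K))
  expect_true(all(K > 0 & K <= p$s2 + 1e-15))
  expect_error(rbf_kernel(matrix(0, 1, 2), matrix(0, 1, 3), p), "dimensions")
  expect_error(kernel_params(0, 1, 1), "positive")
})

test_that("log marginal likelihood matches dense-formula oracles", {
  p <- kernel_params(2, 1.3, 0.4)
  # univariate: log N(y; 0, s2 + sigma2)
  expect_equal(log_marginal_likelihood(matrix(0.3), 1.1, p),
               dnorm(1.1, 0, sqrt(2.4), log = TRUE), tolerance = 1e-8)

  set.seed(72)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    y <- rnorm(n)
    K <- rbf_kernel(X, NULL, p) + diag(p$sigma2, n)
    dense <- -0.5 * drop(t(y) %*% solve(K) %*% y) -
      0.5 * determinant(K)$modulus[1] - n / 2 * log(2 * pi)
    expect_equal(log_marginal_likelihood(X, y, p), dense, tolerance = 1e-8)
  }

  # zero targets: only the determinant term remains
  X <- matrix(rnorm(6), 3, 2)
  K <- rbf_kernel(X, NULL, p) + diag(p$sigma2, 3)
  expect_equal(log_marginal_likelihood(X, rep(0, 3), p),
               -0.5 * determinant(K)$modulus[1] - 1.5 * log(2 * pi),
               tolerance = 1e-8)
})

test_that("the cached training solve is consistent with the parameters", {
  set.seed(73)
  X <- matrix(runif(30), 10, 3)
  y <- rnorm(10)
  ck <- gpr_clock(X, y, kernel_params(1.5, 0.8, 0.2))
  K <- rbf_kernel(X, NULL, ck$params) + diag(ck$params$sigma2 + ck$jitter, 10)
  expect_equal(as.vector(K %*% ck$alpha), y - ck$y_offset, tolerance = 1e-10)
})

test_that("posterior mean and variance match the dense-inverse oracle", {
  # hand case: one training point, y_centered = 1, s2 = l = sigma2 = 1
  ck <- gpr_clock(matrix(0), 1, kernel_params(1, 1, 1), center = FALSE)
  pr <- predict_gpr(ck, matrix(0))
  expect_equal(pr$mu, 0.5, tolerance = 1e-8)
  expect_equal(pr$variance, 0.5, tolerance = 1e-8)
  expect_equal(pr$lower, pr$mu - 2 * sqrt(pr$variance), tolerance = 1e-12)
  expect_equal(pr$upper, pr$mu + 2 * sqrt(pr$variance), tolerance = 1e-12)

  set.seed(74)
  for (i in 1:20) {
    n <- sample(2:5, 1); d <- sample(1:3, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- rnorm(n)
    params <- kernel_params(exp(runif(1, -1, 1)), exp(runif(1, -1, 0.5)),
                            exp(runif(1, -2, 0)))
    Xnew <- matrix(rnorm(3 * d), 3, d)
    ck <- gpr_clock(X, y, params, center = FALSE)
    pr <- predict_gpr(ck, Xnew)
    oracle <- gp_posterior_oracle(X, y, Xnew, params)
    expect_equal(pr$mu, oracle$mu, tolerance = 1e-8)
    expect_equal(pr$variance, pmax(oracle$var, 0), tolerance = 1e-8)
  }
})

test_that("variance rises monotonically to the s2 ceiling off-distribution", {
  set.seed(75)
  X <- matrix(runif(40, 0, 1), 20, 2)
  y <- rowSums(X) * 10 + rnorm(20, 0, 0.5)
  params <- kernel_params(25, 0.5, 0.25)
  ck <- gpr_clock(X, y, params)
  # outbound ray from the training centroid
  centre <- colMeans(X)
  dirn <- c(1, 1) / sqrt(2)
  dists <- seq(1, 12, length.out = 24)
  ray <- t(vapply(dists, function(t) centre + t * dirn, numeric(2)))
  pr <- predict_gpr(ck, ray)
  expect_true(all(diff(pr$variance) >= -1e-10))
  far <- predict_gpr(ck, matrix(centre + 20 * params$l * 30 * dirn, 1))
  expect_equal(far$variance, params$s2, tolerance = 1e-6)
  expect_equal(far$mu, ck$y_offset, tolerance = 1e-6)
})

test_that("the noise-free limit interpolates the training targets", {
  set.seed(76)
  X <- matrix(runif(16), 8, 2)
  y <- rnorm(8, 50, 5)
  ck <- gpr_clock(X, y, kernel_params(100, 0.7, 1e-8))
  pr <- predict_gpr(ck, X)
  expect_equal(pr$mu, y, tolerance = 1e-3)
  expect_true(all(pr$variance >= 0))
})

test_that("fitting is deterministic and recovers known hyperparameters", {
  set.seed(77)
  n <- 120
  X <- matrix(rnorm(n * 2), n, 2)
  true <- kernel_params(4, 0.5, 0.1)
  K <- rbf_kernel(X, NULL, true)
  diag(K) <- diag(K) + true$sigma2
  y <- as.vector(t(chol(K)) %*% rnorm(n))

  f1 <- fit_gpr(X, y, restarts = 3, seed = 2)
  f2 <- fit_gpr(X, y, restarts = 3, seed = 2)
  expect_identical(f1$params, f2$params)
  expect_lt(abs(log2(f1$params$s2 / true$s2)), 1)
  expect_lt(abs(log2(f1$params$l / true$l)), 1)
  expect_lt(abs(log2(f1$params$sigma2 / true$sigma2)), 1)
})

test_that("pure-noise targets are absorbed by the white-noise kernel", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(runif(200), 100, 2)
    y <- rnorm(100)
    f <- fit_gpr(X, y, restarts = 3, seed = s)
    expect_gte(f$params$sigma2, f$params$s2)
  }
})

test_that("drift-course samples get wider credible intervals than held-out aging samples", {
  d <- make_aging(n = 80, p = 40, k = 15, seed = 78)
  sp <- split_train_test(d, 0.25, seed = 78)
  ck <- fit_gpr(sp$train, restarts = 3, seed = 8)
  in_dist <- predict_gpr(ck, sp$test)
  course <- simulate_reprogramming_course(
    simulation_config(15, 40, 15, noise_sd = 0.03, seed = 78),
    days = c(28), drift_per_day = 0.04, seed = 79)
  ood <- predict_gpr(ck, course)
  expect_gt(mean(ood$upper - ood$lower), mean(in_dist$upper - in_dist$lower))
  # interval half-width is two posterior standard deviations
  expect_equal(in_dist$upper - in_dist$mu, 2 * sqrt(in_dist$variance),
               tolerance = 1e-12)
})

test_that("query dimension and CpG mismatches are rejected", {
  d <- make_aging(n = 30, p = 10, k = 3, seed = 79)
  ck <- gpr_clock(d, params = kernel_params(10, 1, 1))
  other <- make_aging(n = 5, p = 4, k = 1, seed = 80)
  expect_error(predict_gpr(ck, other), "absent")
  expect_error(predict_gpr(ck, matrix(0.5, 2, 3)), "dimension")
})
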