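test_that("lasso clock recovers a single noiseless predictor", {
  set.seed(51)
  n <- 60
  beta <- cbind(cg1 = runif(n, 0.2, 0.8),
                matrix(runif(n * 50), n,
                       dimnames = list(NULL, sprintf("decoy%02d", 1:50))))
  d <- methylation_dataset(beta, age = 5 + 200 * beta[, "cg1"])
  clk <- fit_lasso_clock(d, alpha = 1e-3)
  expect_identical(names(clk$coefficients), "cg1")
  expect_equal(unname(clk$coefficients), 200, tolerance = 0.05)
  expect_equal(clk$cv_folds, NA_integer_)

  cv <- fit_lasso_clock(d, seed = 1)
  expect_equal(cv$cv_folds, 5L)  # 5-fold CV is the default
  expect_true("cg1" %in% names(cv$coefficients))
})

test_that("a huge penalty empties the support and leaves the mean", {
  d <- make_aging(n = 50, p = 20, k = 5, seed = 52)
  clk <- fit_lasso_clock(d, alpha = 1e6)
  expect_length(clk$coefficients, 0)
  expect_equal(clk$intercept, mean(d$age))
  expect_equal(apply_clock(clk, d)$mu, rep(mean(d$age), 50))
})

test_that("degenerate training inputs are rejected", {
  d <- make_aging(n = 10, p = 5, k = 2, seed = 53)
  d$age <- rep(40, 10)
  expect_error(fit_lasso_clock(d), "constant age")
  d2 <- make_aging(n = 4, p = 5, k = 2, seed = 53)
  expect_error(fit_lasso_clock(d2, folds = 5), "5-fold")
})

test_that("apply_clock is the documented dot product and checks support", {
  beta <- matrix(0.5, 1, 1, dimnames = list("s1", "cg1"))
  d <- methylation_dataset(beta)
  clk <- linear_clock(c(cg1 = 10), intercept = 5)
  expect_equal(apply_clock(clk, d)$mu, 10)

  other <- methylation_dataset(matrix(0.5, 1, 1,
                                      dimnames = list("s1", "cgX")))
  expect_error(apply_clock(clk, other), "cg1")
})

test_that("apply_clock is linear in the sample", {
  d <- make_aging(n = 30, p = 25, k = 8, seed = 54)
  clk <- fit_lasso_clock(d, seed = 2)
  x1 <- d$beta[1, , drop = FALSE]
  x2 <- d$beta[2, , drop = FALSE]
  lam <- 0.3
  mix <- lam * x1 + (1 - lam) * x2
  rownames(mix) <- "mix"
  pred <- function(x) apply_clock(clk, methylation_dataset(x))$mu
  expect_equal(pred(mix), lam * pred(x1) + (1 - lam) * pred(x2),
               tolerance = 1e-10)
})

test_that("regression metrics match hand and textbook computations", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$mae, 0)
  expect_equal(m$r2, 1)
  expect_equal(m$pearson_r, 1)

  mean_pred <- regression_metrics(c(1, 2, 3, 4), rep(2.5, 4))
  expect_equal(mean_pred$r2, 0)
  expect_true(mean_pred$degenerate)

  hand <- regression_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(hand$mae, 2 / 3)
  expect_equal(hand$r2, 0)
  expect_true(is.na(hand$pearson_r))

  set.seed(55)
  for (i in 1:10) {
    y <- rnorm(20); yh <- y + rnorm(20, 0, 0.5)
    m <- regression_metrics(y, yh)
    e <- yh - y
    expect_equal(m$mae, mean(abs(e)), tolerance = 1e-12)
    expect_equal(m$medae, median(abs(e)), tolerance = 1e-12)
    expect_equal(m$r2, 1 - sum(e^2) / sum((y - mean(y))^2), tolerance = 1e-12)
    expect_equal(m$pearson_r,
                 sum((y - mean(y)) * (yh - mean(yh))) /
                   sqrt(sum((y - mean(y))^2) * sum((yh - mean(yh))^2)),
                 tolerance = 1e-12)
  }
})

test_that("rejuvenation delta is the group-mean difference", {
  preds <- data.frame(sample_id = letters[1:4], mu = c(50, 50, 10, 10),
                      group = c("0", "0", "15", "15"))
  expect_equal(rejuvenation_delta(preds, "0", "15"), -40)
  expect_equal(rejuvenation_delta(preds, "0", "0"), 0)
  expect_error(rejuvenation_delta(preds, "0", "99"), "absent")
})

test_that("model families are pluggable and disagree on a drift course", {
  d <- make_aging(n = 120, p = 80, k = 20, seed = 56)
  sp <- split_train_test(d, 0.3, seed = 56)
  course <- simulate_reprogramming_course(
    simulation_config(20, 80, 20, noise_sd = 0.03, seed = 56),
    days = c(0, 15), drift_per_day = 0.02, seed = 57)

  constant_family <- list(
    name = "constant",
    fit = function(x, y, seed = 1) mean(y),
    predict = function(model, x) rep(model, nrow(x))
  )
  res <- compare_model_families(
    sp$train, sp$test, course = course,
    families = list(lasso_family(), knn_family(), constant_family),
    t0 = "0", t1 = "15", seed = 3)
  expect_equal(nrow(res), 3)
  expect_false(any(res$failed))
  expect_gt(res$r2[res$family == "lasso"], 0.9)
  expect_equal(res$delta[res$family == "constant"], 0)
  # model-choice uncertainty: family deltas are not all equal
  expect_gt(sd(res$delta[res$family %in% c("lasso", "knn")]), 0)

  failing_family <- list(name = "broken",
                         fit = function(x, y, seed = 1) stop("nope"),
                         predict = function(model, x) NULL)
  res2 <- compare_model_families(sp$train, sp$test,
                                 families = list(failing_family), seed = 3)
  expect_true(res2$failed)
})

test_that("clock serialization round-trips coefficients and metadata", {
  d <- make_aging(n = 50, p = 30, k = 8, seed = 58)
  clk <- fit_lasso_clock(d, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_clock(clk, path)
  back <- read_clock(path)
  expect_equal(back$coefficients, clk$coefficients)
  expect_equal(back$intercept, clk$intercept)
  expect_equal(back$alpha, clk$alpha)
  expect_identical(back$age_unit, clk$age_unit)
  expect_equal(apply_clock(back, d)$mu, apply_clock(clk, d)$mu)
})
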