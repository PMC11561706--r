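test_that("simulation_config rejects invalid settings", {
  expect_error(simulation_config(0, 10, 5), "counts")
  expect_error(simulation_config(10, 10, 11), "n_age_cpgs")
  expect_error(simulation_config(10, 10, 5, age_range = c(50, 50)),
               "non-degenerate")
  expect_error(simulation_config(10, 10, 5, noise_sd = -0.1), "noise_sd")
})

test_that("aging generator is deterministic and bounded", {
  cfg <- simulation_config(40, 30, 10, noise_sd = 0.05, seed = 3)
  d1 <- simulate_aging_methylation(cfg)
  d2 <- simulate_aging_methylation(cfg)
  expect_identical(d1, d2)
  expect_true(all(d1$beta >= 0 & d1$beta <= 1))
  d3 <- simulate_aging_methylation(
    simulation_config(40, 30, 10, noise_sd = 0.05, seed = 4))
  expect_false(identical(d1$beta, d3$beta))
})

test_that("a noiseless age-CpG is perfectly correlated with age", {
  cfg <- simulation_config(30, 3, 1, noise_sd = 0,
                           slope_range = c(0.005, 0.005), seed = 1)
  d <- simulate_aging_methylation(cfg)
  r <- cor(d$beta[, d$age_cpgs], d$age)
  expect_equal(abs(r), 1)
})

test_that("true age-CpGs carry strong signal at the reference config", {
  d <- simulate_aging_methylation(
    simulation_config(200, 500, 50, noise_sd = 0.03, seed = 7))
  r <- abs(cor(d$beta[, d$age_cpgs], d$age))
  expect_gt(mean(r), 0.8)
})

test_that("a null shift is the bitwise identity and shifts are local", {
  d <- make_aging(seed = 5)
  null_shift <- apply_covariate_shift(
    d, shift_spec(offset = 0, response_offset = 0), seed = 9)
  expect_identical(null_shift$beta, d$beta)
  expect_identical(null_shift$age, d$age)

  half <- suppressWarnings(
    apply_covariate_shift(d, shift_spec(offset = 0.2, fraction_shifted = 0.5),
                          seed = 9))
  untouched <- setdiff(cpg_ids(d), half$shifted_cpgs)
  expect_length(half$shifted_cpgs, round(0.5 * n_cpgs(d)))
  expect_identical(half$beta[, untouched], d$beta[, untouched])
  expect_false(identical(half$beta[, half$shifted_cpgs],
                         d$beta[, half$shifted_cpgs]))
})

test_that("response shift moves ages and saturation is flagged", {
  d <- make_aging(seed = 6)
  resp <- apply_covariate_shift(
    d, shift_spec(offset = 0, response_offset = 12), seed = 1)
  expect_equal(resp$age, d$age + 12)
  expect_warning(
    apply_covariate_shift(d, shift_spec(offset = 0.9,
                                        direction = "toward_extremes"),
                          seed = 1),
    "saturated"
  )
})

test_that("reprogramming course drifts monotonically toward the extremes", {
  base <- simulation_config(25, 60, 15, noise_sd = 0.03, seed = 11)
  course <- simulate_reprogramming_course(base, days = c(0, 10, 20),
                                          drift_per_day = 0.02, seed = 12)
  expect_null(course$age)
  expect_equal(unique(course$group), c("0", "10", "20"))
  day0_mean <- colMeans(course$beta[course$group == "0", ])
  dev <- vapply(c("0", "10", "20"), function(g) {
    mean(abs(sweep(course$beta[course$group == g, ], 2, day0_mean)))
  }, numeric(1))
  expect_true(all(diff(dev) > 0))

  expect_error(simulate_reprogramming_course(base, days = c(0, 10),
                                             drift_per_day = -0.01),
               "drift_per_day")
  expect_error(simulate_reprogramming_course(base, days = c(10, 0),
                                             drift_per_day = 0.01),
               "sorted")
})

test_that("zero drift makes all days exchangeable with day 0", {
  base <- simulation_config(10, 20, 5, noise_sd = 0, seed = 2)
  course <- simulate_reprogramming_course(base, days = c(0, 15, 28),
                                          drift_per_day = 0, seed = 3)
  d0 <- course$beta[course$group == "0", ]
  for (g in c("15", "28")) {
    expect_equal(unname(course$beta[course$group == g, ]), unname(d0))
  }
})

test_that("KS rejections increase along a drifting course", {
  base <- simulation_config(50, 300, 30, noise_sd = 0.03, seed = 13)
  aging <- simulate_aging_methylation(base)
  course <- simulate_reprogramming_course(base, days = c(0, 15, 28),
                                          drift_per_day = 0.02, seed = 14)
  frac <- vapply(c("0", "15", "28"), function(g) {
    day <- subset_samples(course, course$group == g)
    ks_shift_test(aging, day, cpgs = cpg_ids(aging))$rejected_fraction
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[["28"]], frac[["0"]])
})

test_that("anthropometric cohorts have the configured size and structure", {
  coh <- simulate_anthropometric_cohorts(seed = 4)
  expect_equal(sum(coh$cohort == "control"), 1000)
  expect_equal(sum(coh$cohort == "shifted"), 1000)
  expect_true(all(coh$height > 0 & coh$weight > 0))
  expect_identical(coh, simulate_anthropometric_cohorts(seed = 4))

  ctrl <- coh[coh$cohort == "control", ]
  shf <- coh[coh$cohort == "shifted", ]
  model <- lm(age ~ height + weight, data = ctrl)
  expect_lt(mean(predict(model, shf)), mean(shf$age))
})

test_that("rejected fraction grows with offset magnitude", {
  d <- make_aging(n = 100, p = 200, k = 20, seed = 15)
  sp <- split_train_test(d, 0.5, seed = 15)
  frac <- vapply(c(0.05, 0.15, 0.3), function(off) {
    shifted <- suppressWarnings(
      apply_covariate_shift(sp$test, shift_spec(offset = off), seed = 17))
    ks_shift_test(sp$train, shifted, cpgs = cpg_ids(d))$rejected_fraction
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[3], frac[1])
})
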