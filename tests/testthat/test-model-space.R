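test_that("the four model specifications have the stated free/fixed patterns", {
  m1 <- build_model(1)
  expect_false(m1$free_starting_point)
  expect_false(m1$valence_dependent_drift)
  m2 <- build_model(2)
  expect_true(m2$free_starting_point)
  expect_false(m2$valence_dependent_drift)
  m3 <- build_model(3)
  expect_false(m3$free_starting_point)
  expect_true(m3$valence_dependent_drift)
  m4 <- build_model(4)
  expect_true(m4$free_starting_point)
  expect_true(m4$valence_dependent_drift)
  expect_error(build_model(5), "one of")
  expect_error(build_model("a"), "one of")
})

test_that("the drift regression reproduces the group-level worked examples", {
  # control group: intercept 0.46, bias 0.17
  expect_equal(drift_rate(drift_regression(0.46, 0.17), 1), 0.63)
  expect_equal(drift_rate(drift_regression(0.46, 0.17), 0), 0.46)
  # threat group: intercept 0.63, bias -0.08
  expect_equal(drift_rate(drift_regression(0.63, -0.08), 1), 0.55)
  expect_equal(drift_rate(drift_regression(0.63, -0.08), 0), 0.63)
  # no valence dependence
  expect_equal(drift_rate(drift_regression(1.3, 0), c(0, 1)), c(1.3, 1.3))
  expect_error(drift_rate(drift_regression(1, 1), 2), "0 or 1")
  expect_error(drift_regression(NaN, 0), "finite")
})

test_that("boundary mapping points drift toward the correct conclusion in every model", {
  reg <- drift_regression(0.5, 0.2)
  # symmetric models: +v on desirable-state trials, -v on undesirable
  expect_equal(effective_drift(build_model(1), reg, c(1, 0)), c(0.5, -0.5))
  expect_equal(effective_drift(build_model(2), reg, c(1, 0)), c(0.5, -0.5))
  # regression models: magnitude from the regression, sign from the state
  expect_equal(effective_drift(build_model(3), reg, c(1, 0)), c(0.7, -0.5))
  expect_equal(effective_drift(build_model(4), reg, c(1, 0)), c(0.7, -0.5))
  mb <- map_boundaries(build_model(4), reg, c(1, 0))
  expect_identical(unique(mb$upper_choice), "desirable")
  expect_identical(unique(mb$lower_choice), "undesirable")
  expect_equal(mb$drift, c(0.7, -0.5))
})

test_that("model 4 with no biases is likelihood-equivalent to model 1", {
  sim <- simulate_ddm_dataset(factory_group_params("control"),
                              quick_design(2, 25, seed = 8))
  lrt <- log(sim$rt_ms)
  up <- as.integer(sim$choice == "desirable")
  de <- as.integer(sim$desirability_code)
  ll4 <- valenceddm:::ddm_loglik_cpp(lrt, up, de, 2.6, 7.4, 0.5, 0.15,
                                     0.45, 0, TRUE, 1e-7)
  ll1 <- valenceddm:::ddm_loglik_cpp(lrt, up, de, 2.6, 7.4, 0.5, 0.15,
                                     0.45, 0, FALSE, 1e-7)
  expect_equal(ll4, ll1, tolerance = 1e-8)
})

test_that("reference group parameters carry the fitted factory-task estimates", {
  gc <- factory_group_params("control")
  expect_equal(c(gc$threshold, gc$nondecision, gc$start, gc$start_range,
                 gc$drift_intercept, gc$drift_bias),
               c(2.67, 7.55, 0.48, 0.18, 0.46, 0.17))
  gt <- factory_group_params("threat")
  expect_equal(c(gt$threshold, gt$nondecision, gt$start, gt$start_range,
                 gt$drift_intercept, gt$drift_bias),
               c(2.47, 7.49, 0.51, 0.19, 0.63, -0.08))
  expect_error(group_params(2.5, 7.5, sd_drift_bias = -1), "non-negative")
})
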