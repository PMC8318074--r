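test_that("evidence centering covers its range and validates counts", {
  expect_equal(center_evidence(6, 10), 0.1)
  expect_equal(center_evidence(10, 10), 0.5)
  expect_equal(center_evidence(0, 10), -0.5)
  expect_error(center_evidence(1, 0), "at least 1")
  expect_error(center_evidence(5, 4), "between 0")
})

test_that("the logistic prediction is monotone, bounded, and anchored at its indifference point", {
  fit <- list(beta0 = 0.23, beta1 = 25.55)
  expect_equal(predict_psychometric(fit, 0.23 / 25.55), 0.5)
  expect_equal(predict_psychometric(list(beta0 = 0, beta1 = 10), 0), 0.5)
  # value at full TV evidence, frozen from a hand evaluation of
  # 1 / (1 + exp(-(25.55 * 0.5 - 0.23)))
  expect_equal(predict_psychometric(fit, 0.5), 0.99999644, tolerance = 1e-7)
  expect_gt(predict_psychometric(list(beta0 = 0, beta1 = 25), 0.5), 0.999)
  x <- seq(-0.5, 0.5, length.out = 101)
  p <- predict_psychometric(fit, x)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("the indifference point is beta0/beta1 with definitional closure", {
  f1 <- list(beta0 = 0, beta1 = 12)
  expect_equal(indifference_point(f1), 0)
  f2 <- list(beta0 = -0.4, beta1 = 20)
  expect_equal(indifference_point(f2), -indifference_point(
    list(beta0 = 0.4, beta1 = 20)))
  expect_equal(predict_psychometric(f2, indifference_point(f2)), 0.5, tolerance = 1e-12)
  expect_error(indifference_point(list(beta0 = 1, beta1 = 0)), "undefined")
})

test_that("fitting recovers the generating logistic within its bootstrap intervals", {
  des <- task_design(40, 80, seed = 61)
  sim <- simulate_psychometric_dataset(0.23, 25.55, des)
  fit <- fit_psychometric(sim, n_boot = 200, seed = 2)
  expect_gte(0.23, fit$ci_beta0[1]); expect_lte(0.23, fit$ci_beta0[2])
  expect_gte(25.55, fit$ci_beta1[1]); expect_lte(25.55, fit$ci_beta1[2])
  # jointly permuting trials leaves the fit unchanged
  set.seed(5)
  shuf <- sim[sample(nrow(sim)), ]
  fit2 <- fit_psychometric(shuf, n_boot = 0)
  expect_equal(fit2$beta0, fit$beta0, tolerance = 1e-8)
  expect_equal(fit2$beta1, fit$beta1, tolerance = 1e-8)
})

test_that("complete separation falls back to a penalized fit with a warning", {
  d <- make_trials("s1", 40, n_observed = 10)
  d$n_tv_observed <- rep(2:8, length.out = 40)
  d$tv_desirable <- TRUE
  d$choice <- "desirable" # every response is TV
  # with every response TV the fit is penalized (separation) and the
  # near-zero fitted slope additionally triggers the sanity warning
  expect_warning(expect_warning(fit <- fit_psychometric(d, n_boot = 10),
                                "separation"),
                 "not positive")
  expect_true(is.finite(fit$beta1))
  expect_true(fit$separation)
})

test_that("slope recovery bias stays below 10% across the parameter grid", {
  for (b0 in c(-0.6, 0, 0.3)) for (b1 in c(20, 25, 30)) {
    est <- vapply(1:10, function(s) {
      des <- task_design(40, 80, seed = 7000 + 97 * s)
      sim <- simulate_psychometric_dataset(b0, b1, des)
      fit_psychometric(sim, n_boot = 0)$beta1
    }, 0)
    expect_lt(abs(mean(est) - b1) / b1, 0.10)
  }
})
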