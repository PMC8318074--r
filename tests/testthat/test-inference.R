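test_that("Gelman-Rubin statistic separates converged from diverging chains", {
  set.seed(42)
  same <- lapply(1:5, function(i) rnorm(1e4))
  expect_lt(gelman_rubin(same), 1.1)
  # zero between-chain variance can only shrink the ratio below 1
  const_ish <- lapply(1:3, function(i) rep(c(-1, 1), 50))
  expect_lte(gelman_rubin(const_ish), 1)
  # one chain offset by 100x its spread must be flagged
  off <- same
  off[[1]] <- off[[1]] + 100
  expect_gt(gelman_rubin(off), 1.1)
  expect_error(gelman_rubin(same[1]), "at least 2")
  expect_error(gelman_rubin(list(rnorm(5), rnorm(5))), "at least 10")
  # matrix chains give one value per parameter
  mats <- lapply(1:3, function(i)
    cbind(a = rnorm(500), b = rnorm(500, if (i == 1) 50 else 0)))
  rh <- gelman_rubin(mats)
  expect_lt(rh["a"], 1.1)
  expect_gt(rh["b"], 1.1)
})

test_that("DIC follows its defining identity", {
  r <- dic_from_deviance(mean_deviance = mean(c(10, 12, 14)),
                         deviance_at_mean = 11)
  expect_equal(r$effective_params, 1)
  expect_equal(r$dic, 13)
  expect_equal(r$dic, r$deviance_at_mean + 2 * r$effective_params)
})

test_that("posterior sampling is seed-deterministic and flags low information", {
  sim <- simulate_ddm_dataset(factory_group_params("control"),
                              quick_design(4, 20, seed = 14))
  cfg <- quick_config(seed = 77)
  p1 <- sample_posterior(sim, build_model(4), cfg)
  p2 <- sample_posterior(sim, build_model(4), cfg)
  expect_identical(p1$chains, p2$chains)
  # all draws respect the parameter supports
  d <- do.call(rbind, p1$chains)
  expect_true(all(d[, "sz"] >= 0 & d[, "sz"] <= 0.6))
  expect_true(all(plogis(d[, "mu_logit_start"]) > 0.05 &
                    plogis(d[, "mu_logit_start"]) < 0.95))
  expect_true(all(exp(d[, "mu_log_threshold"]) > 0.3))
  # DIC is deterministic given identical chains
  expect_equal(compute_dic(p1)$dic, compute_dic(p2)$dic)

  tiny <- simulate_ddm_dataset(factory_group_params("control"),
                               quick_design(1, 4, seed = 15))
  expect_warning(sample_posterior(tiny, build_model(4),
                                  quick_config(seed = 3, n_samples = 120,
                                               n_burn = 40)),
                 "low information")
  expect_error(sample_posterior(sim, build_model(4),
                                mcmc_config(n_samples = 100, n_burn = 100)),
               "n_burn")
})

test_that("posterior-predictive datasets reproduce the generating point and are seeded", {
  sp <- data.frame(subject_id = 1:6, threshold = 2.4, nondecision = 7.4,
                   start = 0.55, drift_intercept = 0.5, drift_bias = 0.3)
  post <- make_point_posterior(sp, sz = 0.1)
  des <- task_design(6, 150, seed = 99)
  pp1 <- posterior_predictive(post, des)
  pp2 <- posterior_predictive(post, des)
  expect_identical(as.data.frame(pp1), as.data.frame(pp2))
  # a point-mass posterior is equivalent to simulating at that point:
  # choice proportions match the closed-form absorption probabilities
  for (dc in c(0, 1)) {
    v <- (0.5 + 0.3 * dc) * (if (dc == 1) 1 else -1)
    cp <- choice_probability(ddm_params(2.4, 7.4, 0.55, 0.1, v))
    i <- pp1$desirability_code == dc
    expect_lt(abs(mean(pp1$choice[i] == "desirable") - cp),
              3 * sqrt(cp * (1 - cp) / sum(i)))
  }
  # rt values are all beyond the point-mass non-decision time
  expect_true(all(log(pp1$rt_ms) > 7.4))
  expect_error(posterior_predictive(post, task_design(5, 10)),
               "must match")
})

test_that("a control-style posterior predicts higher accuracy on desirable trials", {
  sp <- data.frame(subject_id = 1:8, threshold = 2.67, nondecision = 7.55,
                   start = 0.48, drift_intercept = 0.46, drift_bias = 0.17)
  post <- make_point_posterior(sp, sz = 0.18)
  pp <- posterior_predictive(post, task_design(8, 200, seed = 100))
  acc <- tapply(pp$correct, pp$desirability_code, mean)
  expect_gt(acc[["1"]], acc[["0"]])
})
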