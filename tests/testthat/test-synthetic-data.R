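test_that("task designs validate their probabilities and counts", {
  d <- task_design(n_subjects = 83, n_trials = 80, p_match = 0.6)
  expect_s3_class(d, "task_design")
  expect_identical(d$n_subjects, 83L)
  expect_error(task_design(0, 80), "positive integer")
  expect_error(task_design(10, 80, p_match = 1.0), "strictly between")
  expect_error(task_design(10, 80, p_match = 0.5), "strictly between")
  expect_error(task_design(10, 80, p_desirable_state = 1.2), "\\[0, 1\\]")
  # same seed gives identical downstream datasets
  gp <- factory_group_params("control")
  d1 <- simulate_ddm_dataset(gp, quick_design(3, 10, seed = 9))
  d2 <- simulate_ddm_dataset(gp, quick_design(3, 10, seed = 9))
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_ddm_dataset(gp, quick_design(3, 10, seed = 10))
  expect_false(identical(d1$rt_ms, d3$rt_ms))
})

test_that("stimulus streams are Bernoulli in the match probability with increasing onsets", {
  des <- task_design(2, 10, p_match = 0.6)
  set.seed(11)
  s <- generate_stream("tv", 1e5, des)
  frac <- mean(s$items == "tv")
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / 1e5))
  expect_true(all(diff(s$onsets_ms) > 0))
  expect_length(s$items, 1e5)
  # single-item streams are a single Bernoulli draw
  set.seed(12)
  singles <- replicate(3000, generate_stream("phone", 1, des)$items)
  expect_lt(abs(mean(singles == "phone") - 0.6), 3 * sqrt(0.24 / 3000))
  s3 <- generate_stream("tv", 3, des)
  expect_length(s3$onsets_ms, 3)
  expect_true(all(diff(s3$onsets_ms) > 0))
  expect_error(generate_stream("tv", 0, des), "at least 1")
})

test_that("diffusion-simulated datasets match the analytic choice probabilities", {
  # single-subject population (zero spreads) so trial parameters are exact
  des <- task_design(1, 1e4, seed = 21)
  base <- list(threshold = 2.2, nondecision = 7.4, sd_log_threshold = 0,
               sd_nondecision = 0, sd_logit_start = 0,
               sd_drift_intercept = 0, sd_drift_bias = 0)

  # zero drift, central start: overall split 50/50
  gp0 <- do.call(group_params, c(base, list(start = 0.5, drift_intercept = 0)))
  sim0 <- simulate_ddm_dataset(gp0, des)
  expect_lt(abs(mean(sim0$choice == "desirable") - 0.5), 3 * sqrt(0.25 / 1e4))

  # no valence bias, central start: accuracy symmetric across valences
  gp1 <- do.call(group_params,
                 c(base, list(start = 0.5, drift_intercept = 0.5)))
  sim1 <- simulate_ddm_dataset(gp1, des)
  acc <- tapply(sim1$correct, sim1$desirability_code, mean)
  expect_lt(abs(acc[["1"]] - acc[["0"]]), 3 * sqrt(2 * 0.2 * 0.8 / 5e3))

  # valence-dependent case: per-valence choice proportions match the
  # closed-form absorption probabilities
  gp2 <- do.call(group_params, c(base, list(start = 0.55,
                                            drift_intercept = 0.4,
                                            drift_bias = 0.2,
                                            start_range = 0.15)))
  sim2 <- simulate_ddm_dataset(gp2, des)
  for (dc in c(0, 1)) {
    v <- (0.4 + 0.2 * dc) * (if (dc == 1) 1 else -1)
    cp <- choice_probability(ddm_params(2.2, 7.4, 0.55, 0.15, v))
    obs <- mean(sim2$choice[sim2$desirability_code == dc] == "desirable")
    n <- sum(sim2$desirability_code == dc)
    expect_lt(abs(obs - cp), 3 * sqrt(cp * (1 - cp) / n))
  }
  # stream bookkeeping is coherent
  expect_true(all(sim2$n_observed >= 1))
  expect_true(all(sim2$n_tv_observed <= sim2$n_observed))
})

test_that("psychometric-path datasets follow the logistic generative model", {
  des <- task_design(10, 400, seed = 31)
  sim <- simulate_psychometric_dataset(0, 0, des)
  expect_true(all(sim$n_observed >= 2))
  # flat logistic: TV judgment is a fair coin regardless of evidence
  tv <- (sim$choice == "desirable") == sim$tv_desirable
  expect_lt(abs(mean(tv) - 0.5), 3 * sqrt(0.25 / nrow(sim)))
  # a stopping rule that cannot reach 2 items errors out
  expect_error(
    simulate_psychometric_dataset(0, 25, des,
                                  stopping_rule = function(n) rep(1L, n)),
    "below 2")
})

test_that("dataset CSV round-trips and malformed files are named", {
  sim <- simulate_ddm_dataset(factory_group_params("control"),
                              quick_design(3, 12, seed = 5))
  path <- tempfile(fileext = ".csv")
  write_dataset_csv(sim, path)
  back <- read_dataset_csv(path)
  expect_equal(back$rt_ms, sim$rt_ms, tolerance = 1e-12)
  expect_identical(back$choice, sim$choice)
  expect_identical(back$correct, sim$correct)
  bad <- read.csv(path)
  bad$choice <- NULL
  path2 <- tempfile(fileext = ".csv")
  write.csv(bad, path2, row.names = FALSE)
  expect_error(read_dataset_csv(path2), "`choice`")
})
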