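test_that("parameter validation rejects impossible diffusion settings", {
  expect_error(ddm_params(-1, 0), "threshold")
  expect_error(ddm_params(2, -1), "nondecision")
  expect_error(ddm_params(2, 0, start = 1), "strictly in")
  expect_error(ddm_params(2, 0, start = 0.9, start_range = 0.3),
               "stay inside")
  expect_error(ddm_params(2, 0, drift = Inf), "finite")
})

test_that("first-passage density is a proper defective density across a parameter grid", {
  for (a in c(1, 2.5, 4)) for (v in c(-1, 0, 1)) for (z in c(0.3, 0.5, 0.7)) {
    p <- ddm_params(a, 0, start = z, drift = v)
    iu <- integrate(function(t) wfpt_density(t, "upper", p), 0, Inf,
                    rel.tol = 1e-9)$value
    il <- integrate(function(t) wfpt_density(t, "lower", p), 0, Inf,
                    rel.tol = 1e-9)$value
    expect_true(all(wfpt_density(seq(0.01, 10, length.out = 40),
                                 "upper", p) >= 0))
    expect_equal(iu + il, 1, tolerance = 1e-4)
    expect_equal(iu, choice_probability(p), tolerance = 1e-4)
  }
  # normalization also holds with starting-point variability
  p <- ddm_params(2.5, 0, start = 0.5, start_range = 0.3, drift = 0.5)
  iu <- integrate(function(t) wfpt_density(t, "upper", p), 0, Inf)$value
  il <- integrate(function(t) wfpt_density(t, "lower", p), 0, Inf)$value
  expect_equal(iu + il, 1, tolerance = 1e-4)
  expect_equal(iu, choice_probability(p), tolerance = 1e-4)
})

test_that("density vanishes before the non-decision time and obeys the symmetries", {
  p <- ddm_params(2.5, 7.5, start = 0.5, drift = 0)
  expect_identical(wfpt_density(c(0, 5, 7.5), "upper", p), c(0, 0, 0))
  # zero drift, central start: both boundaries equally likely at every time
  tt <- 7.5 + seq(0.05, 8, length.out = 50)
  expect_equal(wfpt_density(tt, "upper", p), wfpt_density(tt, "lower", p))
  # reflection: z -> 1 - z, v -> -v swaps the boundaries exactly
  for (v in c(-0.8, 0.4)) for (z in c(0.35, 0.6)) {
    pu <- ddm_params(2.2, 1, start = z, drift = v)
    pl <- ddm_params(2.2, 1, start = 1 - z, drift = -v)
    expect_identical(wfpt_density(tt, "upper", pu),
                     wfpt_density(tt, "lower", pl))
  }
  expect_error(wfpt_density(c(1, NA), "upper", p), "finite")
})

test_that("absorption probability has the right limits and matches the path oracle", {
  expect_equal(choice_probability(ddm_params(2, 0, start = 0.37)), 0.37)
  # frozen value verified against a 1e6-path Euler-Maruyama run
  expect_equal(choice_probability(ddm_params(1, 0, start = 0.5, drift = 1)),
               0.7310586, tolerance = 1e-6)
  expect_equal(choice_probability(ddm_params(1, 0, start = 0.5, drift = 40)),
               1, tolerance = 1e-10)
  set.seed(101)
  for (p in list(ddm_params(1, 0, 0.5, 0, 1),
                 ddm_params(2.67, 0, 0.48, 0.18, 0.63))) {
    fp <- simulate_first_passage(p, n = 1e5, dt = 1e-3)
    cp <- choice_probability(p)
    se <- sqrt(cp * (1 - cp) / 1e5)
    expect_lt(abs(mean(fp$boundary == "upper") - cp), 3 * se)
    expect_true(all(fp$decision_time > 0))
  }
  # zero drift: absorption frequency equals the starting point
  fp <- simulate_first_passage(ddm_params(1.5, 0, start = 0.9), n = 1e5)
  expect_lt(abs(mean(fp$boundary == "upper") - 0.9), 3 * sqrt(0.09 / 1e5))
  expect_error(simulate_first_passage(ddm_params(1, 0), n = 5, dt = 0),
               "positive")
})

test_that("path-simulator first-passage times match the density (KS distance)", {
  p <- ddm_params(2.5, 0, start = 0.5, drift = 0.5)
  set.seed(7)
  fp <- simulate_first_passage(p, n = 1e5, dt = 1e-3)
  tu <- sort(fp$decision_time[fp$boundary == "upper"])
  pu <- choice_probability(p)
  cdf <- vapply(quantile(tu, seq(0.02, 0.98, by = 0.04)), function(q)
    integrate(function(t) wfpt_density(t, "upper", p), 0, q)$value / pu, 0)
  emp <- vapply(quantile(tu, seq(0.02, 0.98, by = 0.04)), function(q)
    mean(tu <= q), 0)
  expect_lt(max(abs(cdf - emp)), 0.01)
})

test_that("trial likelihood matches the density, the quadrature matches Monte Carlo, and impossible data give -Inf", {
  p <- ddm_params(2.5, 7.5, start = 0.45, drift = 0.4)
  tt <- 7.5 + c(0.2, 0.8, 2.5)
  expect_equal(exp(trial_loglik(tt, "upper", p)),
               wfpt_density(tt, "upper", p))
  expect_equal(exp(trial_loglik(tt, "lower", p)),
               wfpt_density(tt, "lower", p))
  # sz > 0: 11-node quadrature against brute-force uniform sampling
  psz <- ddm_params(2.5, 7.5, start = 0.5, start_range = 0.2, drift = 0.4)
  set.seed(3)
  ws <- runif(1e5, 0.5 - 0.1, 0.5 + 0.1)
  mc <- rowMeans(vapply(ws, function(w)
    wfpt_density(tt, "upper", ddm_params(2.5, 7.5, start = w, drift = 0.4)),
    numeric(length(tt))))
  expect_equal(exp(trial_loglik(tt, "upper", psz)), mc, tolerance = 1e-3)
  expect_identical(trial_loglik(c(7.5, 7.0), "upper", p), c(-Inf, -Inf))
  expect_error(trial_loglik(7.8, "sideways", p), "upper")
})
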