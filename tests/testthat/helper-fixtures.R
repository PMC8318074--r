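# Small programmatic fixtures shared across test files.

quick_design <- function(n_subjects = 6, n_trials = 30, seed = 1, ...) {
  task_design(n_subjects = n_subjects, n_trials = n_trials, seed = seed, ...)
}

quick_config <- function(seed = 1, n_samples = 300, n_burn = 100, ...) {
  mcmc_config(n_samples = n_samples, n_burn = n_burn, seed = seed, ...)
}

# hand-built trial table with known exclusion structure
make_trials <- function(subject_id, n, n_observed = 8, correct = TRUE,
                        desirability_code = rep_len(c(1, 0), n),
                        group = "control") {
  data.frame(subject_id = subject_id, group = group, trial_index = seq_len(n),
             true_state = ifelse(desirability_code == 1, "desirable",
                                 "undesirable"),
             desirability_code = desirability_code,
             n_observed = rep_len(n_observed, n),
             n_tv_observed = pmin(rep_len(n_observed, n), 4),
             choice = ifelse(xor(desirability_code == 1,
                                 rep_len(correct, n)),
                             "undesirable", "desirable"),
             rt_ms = rep(3000, n), correct = rep_len(correct, n),
             stringsAsFactors = FALSE)
}

# degenerate posterior object: every retained draw equals the given
# subject-level parameter table (natural scales), for predictive and
# correlation tests that need a posterior with known content
make_point_posterior <- function(subject_params, sz = 0.18,
                                 spec = build_model(4), n_draws = 20) {
  S <- nrow(subject_params)
  lay <- valenceddm:::.param_layout(spec, default_priors())
  ids <- subject_params$subject_id
  cols <- valenceddm:::.chain_colnames(lay, ids)
  m <- matrix(0, n_draws, length(cols), dimnames = list(NULL, cols))
  m[, "sz"] <- sz
  for (i in seq_len(S)) {
    s <- ids[i]
    m[, paste0("log_threshold[", s, "]")] <- log(subject_params$threshold[i])
    m[, paste0("nondecision[", s, "]")] <- subject_params$nondecision[i]
    if (spec$free_starting_point)
      m[, paste0("logit_start[", s, "]")] <- qlogis(subject_params$start[i])
    m[, paste0("drift_intercept[", s, "]")] <-
      subject_params$drift_intercept[i]
    if (spec$valence_dependent_drift)
      m[, paste0("drift_bias[", s, "]")] <- subject_params$drift_bias[i]
  }
  m[, "mu_log_threshold"] <- mean(log(subject_params$threshold))
  m[, "mu_nondecision"] <- mean(subject_params$nondecision)
  if (spec$free_starting_point)
    m[, "mu_logit_start"] <- mean(qlogis(subject_params$start))
  m[, "mu_drift_intercept"] <- mean(subject_params$drift_intercept)
  if (spec$valence_dependent_drift)
    m[, "mu_drift_bias"] <- mean(subject_params$drift_bias)
  structure(list(chains = list(m), spec = spec,
                 config = quick_config(), priors = default_priors(),
                 subjects = ids, layout = lay, data = NULL, rhat = NULL),
            class = "ddm_posterior")
}
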