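#' MCMC settings for hierarchical estimation
#'
#' @param n_samples Total sweeps per chain (burn-in included).  The
#'   full-scale analysis uses 20,000; recovery runs use 2,000.
#' @param n_burn Burn-in sweeps discarded (full scale 5,000; recovery 500).
#' @param thin Keep every `thin`-th post-burn-in sweep (full scale 5).
#' @param n_chains Number of chains (5 for convergence diagnostics).
#' @param seed Integer seed; chains derive their own sub-seeds from it.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_samples = 2000, n_burn = 500, thin = 1,
                        n_chains = 1, seed = 1) {
  if (n_burn >= n_samples) stop("`n_burn` must be smaller than `n_samples`")
  if (thin < 1) stop("`thin` must be at least 1")
  if (n_chains < 1) stop("`n_chains` must be at least 1")
  structure(list(n_samples = as.integer(n_samples),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
paper_mcmc_config <- function(seed = 1) {
  mcmc_config(n_samples = 20000, n_burn = 5000, thin = 5, n_chains = 5,
              seed = seed)
}

# sampling-scale parameter layout for a model specification
.param_layout <- function(spec, priors) {
  nm <- c("log_threshold", "nondecision",
          if (spec$free_starting_point) "logit_start", "drift_intercept",
          if (spec$valence_dependent_drift) "drift_bias")
  list(names = nm,
       lo = vapply(nm, function(p) priors[[p]][1], 0),
       hi = vapply(nm, function(p) priors[[p]][2], 0))
}

.chain_colnames <- function(layout, subjects) {
  c(paste0("mu_", layout$names), paste0("sig_", layout$names), "sz",
    as.vector(t(outer(subjects, layout$names,
                      function(s, p) paste0(p, "[", s, "]")))),
    "deviance")
}

# per-subject trial lists on the scales the sampler uses
.subject_lists <- function(data) {
  need <- c("subject_id", "rt_ms", "choice", "desirability_code")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  ids <- unique(data$subject_id)
  by <- split(data, factor(data$subject_id, levels = ids))
  list(ids = ids,
       log_rt = lapply(by, function(d) log(d$rt_ms)),
       upper = lapply(by, function(d) as.integer(d$choice == "desirable")),
       desir = lapply(by, function(d) as.integer(d$desirability_code)))
}

#' Hierarchical Bayesian estimation of a diffusion model
#'
#' Fits one model specification to one group's trial data by
#' Metropolis-within-Gibbs MCMC.  Subject-level parameters (on log / logit /
#' identity sampling scales) are drawn from group-level normal
#' distributions whose means carry flat priors over generous ranges and
#' whose spreads carry half-normal priors; the across-trial starting-point
#' range `sz` is a single group-level scalar.  Subject parameters both
#' contribute to and are constrained by the group-level estimates.
#'
#' @param data A `behavioral_dataset` (or data.frame with columns
#'   `subject_id`, `rt_ms`, `choice`, `desirability_code`), a single group.
#' @param spec A [build_model()] specification.
#' @param config An [mcmc_config()].
#' @param priors Prior ranges from [default_priors()].
#' @param eps Truncation tolerance of the first-passage density series.
#' @return An object of class `ddm_posterior`: retained chains (one matrix
#'   per chain, one column per parameter plus the deviance), the model
#'   spec, config, subject ids, per-parameter Gelman-Rubin statistics when
#'   `n_chains >= 2`, and the data needed for [compute_dic()] and
#'   [posterior_predictive()].
#' @examples
#' \donttest{
#' d <- task_design(n_subjects = 6, n_trials = 30, seed = 1)
#' sim <- simulate_ddm_dataset(factory_group_params("control"), d)
#' post <- sample_posterior(sim, build_model(4),
#'                          mcmc_config(n_samples = 400, n_burn = 100))
#' summary(post)
#' }
#' @export
sample_posterior <- function(data, spec, config = mcmc_config(),
                             priors = default_priors(), eps = 1e-7) {
  stopifnot(inherits(spec, "ddm_model_spec"), inherits(config, "mcmc_config"))
  if ("group" %in% names(data) && length(unique(data$group)) > 1)
    stop("`data` must contain a single group; fit groups separately")
  sl <- .subject_lists(data)
  S <- length(sl$ids)
  ntr <- lengths(sl$log_rt)
  if (any(ntr < 2)) stop("each subject needs at least 2 trials")
  if (any(ntr < 10))
    warning("subject(s) with fewer than 10 trials: posterior will be ",
            "dominated by the group-level prior (low information)")
  lay <- .param_layout(spec, priors)
  np <- length(lay$names)
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1, config$n_chains)
  sz0 <- 0.1

  init_theta <- function() {
    th <- matrix(0, S, np, dimnames = list(NULL, lay$names))
    for (s in seq_len(S)) {
      ok <- FALSE
      for (try in 1:20) {
        jit <- rnorm(np, 0, 0.05 * try)
        v <- c(log(2.5), max(0.05, min(sl$log_rt[[s]]) - 0.5),
               if (spec$free_starting_point) 0, 0.5,
               if (spec$valence_dependent_drift) 0) + jit
        v <- pmin(pmax(v, lay$lo + 1e-6), lay$hi - 1e-6)
        z <- if (spec$free_starting_point)
          plogis(v[which(lay$names == "logit_start")]) else 0.5
        b0 <- v[which(lay$names == "drift_intercept")]
        b1 <- if (spec$valence_dependent_drift)
          v[which(lay$names == "drift_bias")] else 0
        ll <- ddm_loglik_cpp(sl$log_rt[[s]], sl$upper[[s]], sl$desir[[s]],
                             exp(v[1]), v[2], z, sz0, b0, b1,
                             spec$valence_dependent_drift, eps)
        if (is.finite(ll)) { th[s, ] <- v; ok <- TRUE; break }
      }
      if (!ok) stop("could not find finite starting values for subject ",
                    sl$ids[s])
    }
    th
  }

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    th <- init_theta()
    m <- hddm_mcmc_cpp(sl$log_rt, sl$upper, sl$desir,
                       spec$free_starting_point,
                       spec$valence_dependent_drift,
                       config$n_samples, config$n_burn, config$thin,
                       colMeans(th), rep(0.2, np), th, sz0,
                       lay$lo, lay$hi, priors$sigma_tau, priors$sz_max, eps)
    colnames(m) <- .chain_colnames(lay, sl$ids)
    chains[[ch]] <- m
  }
  rhat <- if (config$n_chains >= 2) {
    cols <- setdiff(colnames(chains[[1]]), "deviance")
    gelman_rubin(lapply(chains, function(m) m[, cols, drop = FALSE]))
  } else NULL
  structure(list(chains = chains, spec = spec, config = config,
                 priors = priors, subjects = sl$ids, layout = lay,
                 data = sl, rhat = rhat,
                 fingerprint = c(n_trials = sum(ntr),
                                 sum_log_rt = sum(unlist(sl$log_rt)))),
            class = "ddm_posterior")
}

.all_draws <- function(posterior) do.call(rbind, posterior$chains)

#' Group-level estimates on the natural scale
#'
#' Posterior means and 95\% credible intervals of the group-level
#' parameters, back-transformed to the natural scale (threshold
#' `exp(mu)`, starting point `plogis(mu)`, others identity).
#'
#' @param posterior A [sample_posterior()] result.
#' @return A data.frame with columns `parameter`, `estimate`, `ci_lower`,
#'   `ci_upper`.
#' @export
group_estimates <- function(posterior) {
  stopifnot(inherits(posterior, "ddm_posterior"))
  d <- .all_draws(posterior)
  spec <- posterior$spec
  tr <- list(threshold = exp(d[, "mu_log_threshold"]),
             nondecision = d[, "mu_nondecision"],
             start = if (spec$free_starting_point)
               plogis(d[, "mu_logit_start"]) else rep(0.5, nrow(d)),
             start_range = d[, "sz"],
             drift_intercept = d[, "mu_drift_intercept"],
             drift_bias = if (spec$valence_dependent_drift)
               d[, "mu_drift_bias"] else rep(0, nrow(d)))
  data.frame(parameter = names(tr),
             estimate = vapply(tr, mean, 0),
             ci_lower = vapply(tr, quantile, 0, probs = 0.025),
             ci_upper = vapply(tr, quantile, 0, probs = 0.975),
             row.names = NULL)
}

#' Subject-level posterior means on the natural scale
#'
#' @param posterior A [sample_posterior()] result.
#' @return A data.frame with one row per subject: `subject_id`,
#'   `threshold`, `nondecision`, `start`, `drift_intercept`, `drift_bias`.
#' @export
subject_estimates <- function(posterior) {
  stopifnot(inherits(posterior, "ddm_posterior"))
  d <- .all_draws(posterior)
  spec <- posterior$spec
  col <- function(p, s) d[, paste0(p, "[", s, "]")]
  ids <- posterior$subjects
  data.frame(
    subject_id = ids,
    threshold = vapply(ids, function(s) mean(exp(col("log_threshold", s))), 0),
    nondecision = vapply(ids, function(s) mean(col("nondecision", s)), 0),
    start = if (spec$free_starting_point)
      vapply(ids, function(s) mean(plogis(col("logit_start", s))), 0)
    else rep(0.5, length(ids)),
    drift_intercept = vapply(ids, function(s)
      mean(col("drift_intercept", s)), 0),
    drift_bias = if (spec$valence_dependent_drift)
      vapply(ids, function(s) mean(col("drift_bias", s)), 0)
    else rep(0, length(ids)),
    row.names = NULL)
}

#' @export
summary.ddm_posterior <- function(object, ...) {
  est <- group_estimates(object)
  if (!is.null(object$rhat)) {
    grp <- grep("^(mu_|sig_)|^sz$", names(object$rhat), value = TRUE)
    attr(est, "max_rhat") <- max(object$rhat[grp])
  }
  est
}

#' @export
print.ddm_posterior <- function(x, ...) {
  cat(sprintf("Hierarchical diffusion posterior: model %d, %d subjects, %d chain(s) x %d retained draws\n",
              x$spec$model_id, length(x$subjects), length(x$chains),
              nrow(x$chains[[1]])))
  print(group_estimates(x))
  if (!is.null(x$rhat))
    cat(sprintf("max R-hat (all parameters): %.3f\n", max(x$rhat)))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction statistic
#'
#' Compares the estimated between-chain and within-chain variances for each
#' parameter; values below 1.1 are conventionally taken as converged.
#'
#' @param chain_set A list of at least two equally sized numeric matrices
#'   (draws x parameters) or numeric vectors, each of length at least 10.
#' @return A named vector of R-hat values (one per parameter).
#' @export
gelman_rubin <- function(chain_set) {
  if (!is.list(chain_set) || length(chain_set) < 2)
    stop("`chain_set` must be a list of at least 2 chains")
  mats <- lapply(chain_set, function(ch) {
    if (is.null(dim(ch))) matrix(ch, ncol = 1, dimnames = list(NULL, "par"))
    else as.matrix(ch)
  })
  n <- unique(vapply(mats, nrow, 0L))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 10) stop("chains must have length at least 10")
  vapply(seq_len(ncol(mats[[1]])), function(j) {
    x <- vapply(mats, function(m) m[, j], numeric(n))
    W <- mean(apply(x, 2, stats::var))
    B_n <- stats::var(colMeans(x)) # = B / n
    if (W == 0) return(if (B_n == 0) 1 else Inf)
    sqrt((n - 1) / n + B_n / W)
  }, 0, USE.NAMES = FALSE) |> setNames(colnames(mats[[1]]))
}

#' Deviance information criterion
#'
#' `DIC = deviance_at_mean + 2 * pD` with
#' `pD = mean_deviance - deviance_at_mean`; lower is better.  The deviance
#' at the mean evaluates each parameter at its posterior mean on the
#' sampling (transformed) scale, a choice DIC is not invariant to.
#'
#' @param posterior A [sample_posterior()] result (which retains the data
#'   it was fit to).
#' @return An object of class `dic_result`: list with `dic`,
#'   `mean_deviance`, `deviance_at_mean` and `effective_params`.
#' @export
compute_dic <- function(posterior) {
  stopifnot(inherits(posterior, "ddm_posterior"))
  d <- .all_draws(posterior)
  mean_dev <- mean(d[, "deviance"])
  spec <- posterior$spec
  sl <- posterior$data
  sz <- mean(d[, "sz"])
  dev_at_mean <- 0
  for (s in posterior$subjects) {
    cm <- function(p) mean(d[, paste0(p, "[", s, "]")])
    i <- match(s, posterior$subjects)
    ll <- ddm_loglik_cpp(
      sl$log_rt[[i]], sl$upper[[i]], sl$desir[[i]],
      exp(cm("log_threshold")), cm("nondecision"),
      if (spec$free_starting_point) plogis(cm("logit_start")) else 0.5,
      sz, cm("drift_intercept"),
      if (spec$valence_dependent_drift) cm("drift_bias") else 0,
      spec$valence_dependent_drift, 1e-7)
    dev_at_mean <- dev_at_mean - 2 * ll
  }
  dic_from_deviance(mean_dev, dev_at_mean)
}

#' @rdname compute_dic
#' @param mean_deviance Posterior mean of the deviance.
#' @param deviance_at_mean Deviance at the posterior-mean parameters.
#' @export
dic_from_deviance <- function(mean_deviance, deviance_at_mean) {
  pd <- mean_deviance - deviance_at_mean
  structure(list(dic = deviance_at_mean + 2 * pd,
                 mean_deviance = mean_deviance,
                 deviance_at_mean = deviance_at_mean,
                 effective_params = pd),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC = %.2f (mean deviance %.2f, pD %.2f)\n",
              x$dic, x$mean_deviance, x$effective_params))
  invisible(x)
}

#' Posterior-predictive simulation
#'
#' Draws a parameter vector (all subject-level parameters plus `sz`) from
#' the retained posterior samples and simulates a full dataset with the
#' same subjects, number of trials and trial structure via the diffusion
#' path simulator.
#'
#' @param posterior A [sample_posterior()] result.
#' @param design A [task_design()] with `n_subjects` equal to the number of
#'   fitted subjects; its `seed` (if any) seeds the simulation.
#' @param group_label Label stored in the `group` column.
#' @param dt Euler step of the path simulator.
#' @return A `behavioral_dataset` data.frame.
#' @export
posterior_predictive <- function(posterior, design,
                                 group_label = "posterior-predictive",
                                 dt = 1e-3) {
  stopifnot(inherits(posterior, "ddm_posterior"),
            inherits(design, "task_design"))
  if (design$n_subjects != length(posterior$subjects))
    stop("`design$n_subjects` must match the number of fitted subjects")
  if (!is.null(design$seed)) set.seed(design$seed)
  d <- .all_draws(posterior)
  row <- d[sample.int(nrow(d), 1), ]
  spec <- posterior$spec
  rows <- lapply(seq_along(posterior$subjects), function(i) {
    s <- posterior$subjects[i]
    g <- function(p) unname(row[paste0(p, "[", s, "]")])
    .simulate_subject(
      s, group_label, exp(g("log_threshold")), g("nondecision"),
      if (spec$free_starting_point) plogis(g("logit_start")) else 0.5,
      unname(row["sz"]), g("drift_intercept"),
      if (spec$valence_dependent_drift) g("drift_bias") else 0,
      spec$valence_dependent_drift, runif(1) < 0.5, design, dt)
  })
  .new_behavioral_dataset(do.call(rbind, rows),
                          provenance = "simulated-from-ddm",
                          generating_params = row)
}
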