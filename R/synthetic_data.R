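#' Design of the factory judgment task
#'
#' Encodes the generative structure of the task: on each trial a hidden
#' state (desirable or undesirable factory) is drawn with probability
#' `p_desirable_state`, and the stimulus stream is Bernoulli with
#' probability `p_match` that each item matches the trial's factory type.
#' Stimulus presentation time is jittered uniformly around `mean_stim_ms`
#' with half-width `stim_jitter_ms`, followed by a fixed `mean_lag_ms` lag.
#'
#' @param n_subjects Number of subjects (positive).
#' @param n_trials Trials per subject (positive; the task uses 80).
#' @param p_match Probability that an item matches the factory type; must
#'   lie strictly between 0.5 and 1 (at 0.5 the stream carries no signal,
#'   at 1 it is deterministic).
#' @param p_desirable_state Probability that a trial's true state is the
#'   desirable one.
#' @param mean_stim_ms Mean stimulus presentation time (ms).
#' @param stim_jitter_ms Half-width of the uniform presentation-time jitter.
#' @param mean_lag_ms Inter-stimulus lag (ms, fixed).
#' @param practice Whether a visible-state practice block preceded the task
#'   (recorded only; practice trials are never simulated).
#' @param seed Integer seed used by the dataset simulators; `NULL` leaves
#'   the RNG state untouched.
#' @return An object of class `task_design`.
#' @examples
#' task_design(n_subjects = 83, n_trials = 80)
#' @export
task_design <- function(n_subjects, n_trials = 80, p_match = 0.6,
                        p_desirable_state = 0.5, mean_stim_ms = 521,
                        stim_jitter_ms = 150, mean_lag_ms = 150,
                        practice = TRUE, seed = NULL) {
  if (!is.numeric(n_subjects) || n_subjects < 1 ||
      n_subjects != round(n_subjects))
    stop("`n_subjects` must be a positive integer")
  if (!is.numeric(n_trials) || n_trials < 1 || n_trials != round(n_trials))
    stop("`n_trials` must be a positive integer")
  if (!is.numeric(p_match) || p_match <= 0.5 || p_match >= 1)
    stop("`p_match` must lie strictly between 0.5 and 1")
  if (!is.numeric(p_desirable_state) || p_desirable_state < 0 ||
      p_desirable_state > 1)
    stop("`p_desirable_state` must lie in [0, 1]")
  if (mean_stim_ms <= 0 || mean_lag_ms < 0 || stim_jitter_ms < 0 ||
      stim_jitter_ms >= mean_stim_ms)
    stop("stimulus timing must be positive with jitter below the mean")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 p_match = p_match, p_desirable_state = p_desirable_state,
                 mean_stim_ms = mean_stim_ms,
                 stim_jitter_ms = stim_jitter_ms,
                 mean_lag_ms = mean_lag_ms, practice = practice,
                 seed = seed),
            class = "task_design")
}

#' Generate one stimulus stream
#'
#' Items are drawn independently, each matching the trial's factory type
#' with probability `p_match`; onsets follow the jittered presentation
#' timing of the design and are strictly increasing, with the first item at
#' time 0.  Uses the current RNG state (seed with [set.seed()]).
#'
#' @param trial_type `"tv"` or `"phone"`: the factory type of the trial.
#' @param length Number of items (at least 1).
#' @param design A [task_design()].
#' @return An object of class `stimulus_stream`: a list with `items`
#'   (character vector of `"tv"`/`"phone"`) and `onsets_ms`.
#' @export
generate_stream <- function(trial_type = c("tv", "phone"), length, design) {
  trial_type <- match.arg(trial_type)
  stopifnot(inherits(design, "task_design"))
  if (length < 1) stop("stream `length` must be at least 1")
  length <- as.integer(length)
  match <- runif(length) < design$p_match
  other <- if (trial_type == "tv") "phone" else "tv"
  items <- ifelse(match, trial_type, other)
  dur <- runif(length, design$mean_stim_ms - design$stim_jitter_ms,
               design$mean_stim_ms + design$stim_jitter_ms) +
    design$mean_lag_ms
  onsets <- cumsum(c(0, dur[-length]))
  structure(list(items = items, onsets_ms = onsets),
            class = "stimulus_stream")
}

# number of items whose onset falls strictly before rt_ms, under the
# design's jittered timing; at least 1, capped for degenerate tails
.count_observed <- function(rt_ms, design, cap = 5000L) {
  lo <- design$mean_stim_ms - design$stim_jitter_ms + design$mean_lag_ms
  vapply(rt_ms, function(rt) {
    if (!is.finite(rt)) return(cap)
    nmax <- min(cap, ceiling(rt / lo) + 1L)
    dur <- runif(nmax, design$mean_stim_ms - design$stim_jitter_ms,
                 design$mean_stim_ms + design$stim_jitter_ms) +
      design$mean_lag_ms
    onsets <- cumsum(c(0, dur[-nmax]))
    max(1L, sum(onsets < rt))
  }, 0) |> as.integer()
}

.new_behavioral_dataset <- function(df, provenance, generating_params = NULL,
                                    subject_params = NULL) {
  structure(df, provenance = provenance,
            generating_params = generating_params,
            subject_params = subject_params,
            class = c("behavioral_dataset", "data.frame"))
}

# draw subject-level sampling-scale parameters from the group distributions
.draw_subjects <- function(gp, spec, n) {
  la <- rnorm(n, log(gp$threshold), gp$sd_log_threshold)
  t0 <- rnorm(n, gp$nondecision, gp$sd_nondecision)
  if (spec$free_starting_point) {
    lz <- rnorm(n, qlogis(gp$start), gp$sd_logit_start)
    for (i in seq_len(n)) { # keep z +/- sz/2 inside (0, 1)
      tries <- 0
      while ((plogis(lz[i]) - gp$start_range / 2 <= 0 ||
              plogis(lz[i]) + gp$start_range / 2 >= 1) && tries < 100) {
        lz[i] <- rnorm(1, qlogis(gp$start), gp$sd_logit_start)
        tries <- tries + 1
      }
    }
  } else lz <- rep(0, n)
  b0 <- rnorm(n, gp$drift_intercept, gp$sd_drift_intercept)
  b1 <- if (spec$valence_dependent_drift)
    rnorm(n, gp$drift_bias, gp$sd_drift_bias) else rep(0, n)
  data.frame(subject_id = seq_len(n), threshold = exp(la), nondecision = t0,
             start = plogis(lz), drift_intercept = b0, drift_bias = b1)
}

# simulate one subject's trials from the diffusion generative process
.simulate_subject <- function(sid, group_label, a, t0, z, sz, b0, b1,
                              has_bias, tv_desirable, design, dt) {
  n <- design$n_trials
  desir <- rbinom(n, 1, design$p_desirable_state)
  vmag <- if (has_bias) b0 + b1 * desir else rep(b0, n)
  veff <- ifelse(desir == 1, vmag, -vmag)
  tdec <- numeric(n)
  up <- integer(n)
  for (v in unique(veff)) {
    i <- veff == v
    sim <- simulate_fp_cpp(sum(i), a, v, z, sz, dt, 30)
    tdec[i] <- sim$decision_time
    up[i] <- sim$boundary
  }
  rt_ms <- exp(t0 + tdec)
  n_obs <- .count_observed(rt_ms, design)
  is_tv <- (desir == 1) == tv_desirable
  p_tv <- ifelse(is_tv, design$p_match, 1 - design$p_match)
  n_tv <- rbinom(n, n_obs, p_tv)
  data.frame(subject_id = sid, group = group_label, trial_index = seq_len(n),
             true_state = ifelse(desir == 1, "desirable", "undesirable"),
             desirability_code = desir, n_observed = n_obs,
             n_tv_observed = n_tv,
             choice = ifelse(up == 1, "desirable", "undesirable"),
             rt_ms = rt_ms, correct = up == desir,
             tv_desirable = tv_desirable, stringsAsFactors = FALSE)
}

#' Simulate a behavioral dataset from the diffusion process
#'
#' Draws subject-level parameters from the group-level distributions of
#' `params`, then samples each trial's judgment and log response time from
#' the two-boundary Wiener process (via the path simulator), with the
#' trial's hidden state drawn from the design and a stimulus count
#' consistent with the realized response time and stimulus timing.  The
#' fitted model ignores the discrete stimulus structure, so streams are
#' attached descriptively (counts of items presentable within the RT); the
#' logistic generative path of [simulate_psychometric_dataset()] is the one
#' to use when the downstream analysis is psychometric.
#'
#' @param params A [group_params()] object.
#' @param design A [task_design()]; its `seed` (if any) seeds the
#'   simulation.
#' @param spec A [build_model()] specification (default: model 4).
#' @param group_label Label stored in the `group` column.
#' @param dt Euler step of the path simulator.
#' @return A `behavioral_dataset` data.frame (one row per trial) with the
#'   drawn subject-level parameters in `attr(, "subject_params")`.
#' @examples
#' d <- task_design(n_subjects = 4, n_trials = 8, seed = 1)
#' sim <- simulate_ddm_dataset(factory_group_params("control"), d)
#' head(sim)
#' @export
simulate_ddm_dataset <- function(params, design, spec = build_model(4),
                                 group_label = "control", dt = 1e-3) {
  stopifnot(inherits(params, "ddm_group_params"),
            inherits(design, "task_design"),
            inherits(spec, "ddm_model_spec"))
  if (!is.null(design$seed)) set.seed(design$seed)
  subj <- .draw_subjects(params, spec, design$n_subjects)
  subj$tv_desirable <- runif(design$n_subjects) < 0.5
  rows <- lapply(seq_len(design$n_subjects), function(s) {
    .simulate_subject(s, group_label, subj$threshold[s], subj$nondecision[s],
                      if (spec$free_starting_point) subj$start[s] else 0.5,
                      params$start_range, subj$drift_intercept[s],
                      subj$drift_bias[s], spec$valence_dependent_drift,
                      subj$tv_desirable[s], design, dt)
  })
  .new_behavioral_dataset(do.call(rbind, rows),
                          provenance = "simulated-from-ddm",
                          generating_params = params, subject_params = subj)
}

#' Simulate a behavioral dataset from the psychometric function
#'
#' For each trial a stimulus stream is generated and truncated at a sampled
#' stopping count (at least 2 items), and the judgment is drawn from the
#' logistic model \eqn{P(TV) = 1 / (1 + e^{-(\beta_1 X - \beta_0)})}, where
#' X is the centered proportion of TV items observed.  One factory type is
#' randomly assigned desirable per subject.
#'
#' @param beta0 Indifference parameter of the generating logistic.
#' @param beta1 Slope of the generating logistic.
#' @param design A [task_design()]; its `seed` (if any) seeds the
#'   simulation.
#' @param stopping_rule Function of a single count returning that many
#'   stopping counts (items observed before responding, all `>= 2`).  The
#'   default draws `2 + NegBinomial(size 3, mean 6)`.  Rules that return
#'   counts below 2 trigger bounded resampling, then an error.
#' @param group_label Label stored in the `group` column.
#' @return A `behavioral_dataset` data.frame, one row per trial.
#' @export
simulate_psychometric_dataset <- function(beta0, beta1, design,
                                          stopping_rule = NULL,
                                          group_label = "control") {
  stopifnot(inherits(design, "task_design"))
  if (!all(is.finite(c(beta0, beta1))))
    stop("psychometric parameters must be finite")
  if (is.null(stopping_rule))
    stopping_rule <- function(n) 2L + stats::rnbinom(n, size = 3, mu = 6)
  if (!is.null(design$seed)) set.seed(design$seed)
  S <- design$n_subjects; n <- design$n_trials
  tv_des <- runif(S) < 0.5
  ntot <- S * n
  n_obs <- stopping_rule(ntot)
  for (tries in 1:10) {
    bad <- n_obs < 2
    if (!any(bad)) break
    n_obs[bad] <- stopping_rule(sum(bad))
  }
  if (any(n_obs < 2))
    stop("`stopping_rule` keeps producing counts below 2")
  sid <- rep(seq_len(S), each = n)
  is_tv <- runif(ntot) < 0.5
  n_tv <- rbinom(ntot, n_obs, ifelse(is_tv, design$p_match,
                                     1 - design$p_match))
  x <- n_tv / n_obs - 0.5
  ch_tv <- runif(ntot) < plogis(beta1 * x - beta0)
  tvd <- tv_des[sid]
  desir <- as.integer(is_tv == tvd)
  rt_ms <- n_obs * (design$mean_stim_ms + design$mean_lag_ms) +
    runif(ntot, -design$stim_jitter_ms, design$stim_jitter_ms)
  df <- data.frame(subject_id = sid, group = group_label,
                   trial_index = rep(seq_len(n), times = S),
                   true_state = ifelse(desir == 1, "desirable",
                                       "undesirable"),
                   desirability_code = desir, n_observed = n_obs,
                   n_tv_observed = n_tv,
                   choice = ifelse(ch_tv == tvd, "desirable", "undesirable"),
                   rt_ms = rt_ms, correct = ch_tv == is_tv,
                   tv_desirable = tvd, stringsAsFactors = FALSE)
  .new_behavioral_dataset(df, provenance = "simulated-from-psychometric",
                          generating_params = list(beta0 = beta0,
                                                   beta1 = beta1))
}

.dataset_columns <- c("subject_id", "group", "trial_index", "true_state",
                      "desirability_code", "n_observed", "n_tv_observed",
                      "choice", "rt_ms", "correct")

#' Write / read a behavioral dataset as CSV
#'
#' The on-disk schema is one row per trial with columns `subject_id, group,
#' trial_index, true_state, desirability_code, n_observed, n_tv_observed,
#' choice, rt_ms, correct` (UTF-8, `.` decimal).  Reading validates the
#' schema and names any missing column.
#'
#' @param data A `behavioral_dataset` (or compatible data.frame).
#' @param path File path.
#' @return `write_dataset_csv` returns `path` invisibly;
#'   `read_dataset_csv` returns a `behavioral_dataset`.
#' @export
write_dataset_csv <- function(data, path) {
  miss <- setdiff(.dataset_columns, names(data))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  write.csv(data[, .dataset_columns], path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(.dataset_columns, names(df))
  if (length(miss))
    stop("malformed dataset CSV: missing column `",
         paste(miss, collapse = "`, `"), "`")
  df$correct <- as.logical(df$correct)
  .new_behavioral_dataset(df, provenance = "external")
}
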