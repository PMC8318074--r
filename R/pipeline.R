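#' Apply the task's exclusion rules
#'
#' Data hygiene in a fixed order: (1) flag trials answered before the
#' second item was observed (`n_observed < 2`); (2) drop subjects flagged
#' on more than half of their trials (exactly half is retained); (3) drop
#' the remaining flagged trials; (4) drop subjects whose accuracy on the
#' retained trials is strictly below chance (0.5; exactly 0.5 is retained).
#' Re-application is idempotent.
#'
#' @param data A `behavioral_dataset` (or data.frame with `subject_id`,
#'   `n_observed`, `correct`).
#' @return A list with `data` (the cleaned dataset) and `report` (class
#'   `exclusion_report`): counts of subjects in, subjects excluded under
#'   each rule, trials dropped, and the excluded ids with reasons.
#' @export
apply_exclusions <- function(data) {
  if (!nrow(data)) stop("dataset is empty")
  need <- c("subject_id", "n_observed", "correct")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))

  flagged <- data$n_observed < 2
  frac <- tapply(flagged, data$subject_id, mean)
  early_ids <- names(frac)[frac > 0.5]
  keep1 <- !(as.character(data$subject_id) %in% early_ids)
  d1 <- data[keep1 & !flagged, , drop = FALSE]
  n_trials_dropped <- sum(keep1 & flagged)

  acc <- tapply(d1$correct, d1$subject_id, mean)
  chance_ids <- names(acc)[acc < 0.5]
  out <- d1[!(as.character(d1$subject_id) %in% chance_ids), , drop = FALSE]

  ids_in <- unique(data$subject_id)
  report <- structure(
    list(n_subjects_in = length(ids_in),
         n_excluded_below_chance = length(chance_ids),
         n_excluded_first_stim_majority = length(early_ids),
         n_trials_dropped_pre_second_item = n_trials_dropped,
         excluded = data.frame(
           subject_id = c(early_ids, chance_ids),
           reason = rep(c("first-stimulus responses in over half of trials",
                          "accuracy below chance"),
                        c(length(early_ids), length(chance_ids))),
           stringsAsFactors = FALSE)),
    class = "exclusion_report")
  list(data = out, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusions: %d subjects in; %d excluded (first-stimulus rule), %d excluded (below chance); %d early trials dropped\n",
              x$n_subjects_in, x$n_excluded_first_stim_majority,
              x$n_excluded_below_chance,
              x$n_trials_dropped_pre_second_item))
  invisible(x)
}

#' Valence-dependent judgment bias per subject
#'
#' The proportion of correctly identified desirable-state trials minus the
#' proportion of correctly identified undesirable-state trials; positive
#' values mean the subject is better at recognizing desirable states.
#'
#' @param data A `behavioral_dataset`.
#' @param subject_id Optional single id; default computes all subjects.
#' @return A data.frame with `subject_id`, `prop_correct_desirable`,
#'   `prop_correct_undesirable` and `bias` (their difference).  Subjects
#'   lacking trials of either valence are dropped with a warning.
#' @export
judgment_bias <- function(data, subject_id = NULL) {
  d <- as.data.frame(data)
  if (!is.null(subject_id)) d <- d[d$subject_id %in% subject_id, ]
  if (!nrow(d)) stop("no trials for the requested subject(s)")
  by <- split(d, d$subject_id)
  rows <- lapply(by, function(s) {
    des <- s$correct[s$desirability_code == 1]
    und <- s$correct[s$desirability_code == 0]
    if (!length(des) || !length(und)) return(NULL)
    data.frame(subject_id = s$subject_id[1],
               prop_correct_desirable = mean(des),
               prop_correct_undesirable = mean(und),
               bias = mean(des) - mean(und))
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped)
    warning(dropped, " subject(s) without trials of both valences dropped")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate model biases with the judgment bias
#'
#' Product-moment correlation between subject-level posterior-mean model
#' biases (the valence-dependent drift-rate bias, or the starting-point
#' bias `z - 0.5`) and the model-free valence-dependent judgment bias.
#'
#' @param posterior A [sample_posterior()] result.
#' @param biases Output of [judgment_bias()] on the same subjects.
#' @param parameter `"drift_bias"` or `"start_bias"`.
#' @return The correlation coefficient; `NA` (with a warning) when either
#'   quantity has zero variance.  Requires at least 3 matched subjects.
#' @export
correlate_bias <- function(posterior, biases,
                           parameter = c("drift_bias", "start_bias")) {
  parameter <- match.arg(parameter)
  est <- subject_estimates(posterior)
  m <- merge(est, biases, by = "subject_id")
  if (nrow(m) < 3) stop("need at least 3 subjects with both quantities")
  x <- if (parameter == "drift_bias") m$drift_bias else m$start - 0.5
  if (sd(x) == 0 || sd(m$bias) == 0) {
    warning("zero variance in one of the quantities; correlation undefined")
    return(NA_real_)
  }
  cor(x, m$bias)
}

#' Permutation test for the group-by-valence interaction
#'
#' Tests whether the valence-dependent judgment bias differs between two
#' groups by permuting group labels across subjects.  The statistic is the
#' difference in group means of the per-subject bias.
#'
#' @param data A `behavioral_dataset` containing exactly two groups.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation draws.
#' @return A list with `statistic`, `p_value` and the group labels.
#' @export
valence_permutation_test <- function(data, n_perm = 2000, seed = 1) {
  groups <- unique(data$group)
  if (length(groups) != 2) stop("`data` must contain exactly two groups")
  bias <- judgment_bias(data)
  glab <- tapply(as.character(data$group), data$subject_id,
                 function(g) g[1])[as.character(bias$subject_id)]
  stat <- function(lab) mean(bias$bias[lab == groups[1]]) -
    mean(bias$bias[lab == groups[2]])
  obs <- stat(glab)
  set.seed(seed)
  null <- replicate(n_perm, stat(sample(glab)))
  list(statistic = obs,
       p_value = (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1),
       groups = groups)
}

#' Simulate-and-refit recovery experiment
#'
#' For each group: simulate a dataset from the group's generating
#' parameters under the valence-dependent model (model 4), refit the model
#' hierarchically, and tabulate recovered group-level posterior means and
#' 95\% credible intervals alongside the generating values.  Optionally
#' also runs the four-model DIC comparison on each simulated dataset.
#'
#' @param params_control,params_threat [group_params()] generating values
#'   (e.g. [factory_group_params()]).
#' @param design A [task_design()]; its seed (offset per group) seeds the
#'   simulations.
#' @param config An [mcmc_config()] for the refits.
#' @param compare_models Also fit models 1-3 and report the DIC table.
#' @return An object of class `recovery_report`: per group, the recovery
#'   table (`parameter`, `generating`, `estimate`, `ci_lower`, `ci_upper`,
#'   `covered`), the fitted posterior, and optionally a DIC table.
#' @export
recovery_experiment <- function(params_control, params_threat, design,
                                config = mcmc_config(),
                                compare_models = FALSE) {
  gen_values <- function(gp) c(threshold = gp$threshold,
                               nondecision = gp$nondecision,
                               start = gp$start,
                               start_range = gp$start_range,
                               drift_intercept = gp$drift_intercept,
                               drift_bias = gp$drift_bias)
  run <- function(gp, label, seed_offset) {
    des <- design
    if (!is.null(des$seed)) des$seed <- des$seed + seed_offset
    sim <- simulate_ddm_dataset(gp, des, build_model(4), group_label = label)
    cfg <- config
    cfg$seed <- config$seed + seed_offset
    post <- sample_posterior(sim, build_model(4), cfg)
    est <- group_estimates(post)
    gen <- gen_values(gp)
    est$generating <- unname(gen[est$parameter])
    est$covered <- est$generating >= est$ci_lower &
      est$generating <= est$ci_upper
    est <- est[, c("parameter", "generating", "estimate", "ci_lower",
                   "ci_upper", "covered")]
    dic <- NULL
    if (compare_models) {
      dic <- data.frame(model_id = 1:4, dic = NA_real_)
      for (m in 1:4) {
        p <- if (m == 4) post else sample_posterior(sim, build_model(m), cfg)
        dic$dic[m] <- compute_dic(p)$dic
      }
    }
    list(label = label, recovery = est, posterior = post, data = sim,
         dic = dic)
  }
  structure(list(control = run(params_control, "control", 0L),
                 threat = run(params_threat, "threat", 1L)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  for (g in c("control", "threat")) {
    cat(sprintf("== %s group ==\n", g))
    print(x[[g]]$recovery, digits = 3)
    if (!is.null(x[[g]]$dic)) {
      cat("DIC comparison:\n")
      print(x[[g]]$dic, digits = 6)
    }
  }
  invisible(x)
}

#' Run the full simulate-fit-recover pipeline
#'
#' End to end: simulate both groups (or ingest a CSV), apply the exclusion
#' rules, fit the psychometric functions per condition, fit the
#' valence-dependent diffusion model per group, compute judgment biases,
#' their correlation with the model biases, and the group-by-valence
#' permutation test; optionally write every stage's output under
#' `out_dir`.
#'
#' @param design A [task_design()] (the seed drives every stage).
#' @param config An [mcmc_config()].
#' @param params_control,params_threat Generating [group_params()].
#' @param csv Optional path to an external trial CSV (schema of
#'   [write_dataset_csv()]); replaces the simulation stage.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param verbose Log stage timings to `stderr`.
#' @return A list with the dataset, exclusion report, psychometric table,
#'   per-group posteriors and group-estimate tables, judgment-bias table,
#'   bias correlations and the permutation test.
#' @export
run_pipeline <- function(design, config = mcmc_config(),
                         params_control = factory_group_params("control"),
                         params_threat = factory_group_params("threat"),
                         csv = NULL, out_dir = NULL, verbose = FALSE) {
  t_start <- proc.time()[["elapsed"]]
  log_stage <- function(msg) if (verbose)
    message(sprintf("[%7.1fs] %s", proc.time()[["elapsed"]] - t_start, msg))

  if (is.null(csv)) {
    log_stage("simulating both groups")
    d1 <- design
    dc <- simulate_ddm_dataset(params_control, d1, group_label = "control")
    d2 <- design
    if (!is.null(d2$seed)) d2$seed <- d2$seed + 1L
    dt_ <- simulate_ddm_dataset(params_threat, d2, group_label = "threat")
    dt_$subject_id <- dt_$subject_id + max(dc$subject_id)
    data <- .new_behavioral_dataset(rbind(as.data.frame(dc),
                                          as.data.frame(dt_)),
                                    provenance = "simulated-from-ddm")
  } else {
    log_stage(paste("reading", csv))
    data <- read_dataset_csv(csv)
  }

  log_stage("applying exclusions")
  ex <- apply_exclusions(data)

  psy <- NULL
  if ("tv_desirable" %in% names(ex$data)) {
    log_stage("fitting psychometric functions")
    psy <- fit_psychometric_conditions(ex$data, seed = config$seed)
  }

  log_stage("fitting valence-dependent diffusion model per group")
  posts <- list(); ests <- list(); biases <- list(); cors <- list()
  for (g in unique(ex$data$group)) {
    dg <- ex$data[ex$data$group == g, ]
    cfg <- config
    cfg$seed <- config$seed + match(g, unique(ex$data$group))
    posts[[g]] <- sample_posterior(dg, build_model(4), cfg)
    ests[[g]] <- group_estimates(posts[[g]])
    biases[[g]] <- judgment_bias(dg)
    cors[[g]] <- c(drift = correlate_bias(posts[[g]], biases[[g]],
                                          "drift_bias"),
                   start = correlate_bias(posts[[g]], biases[[g]],
                                          "start_bias"))
  }

  perm <- if (length(unique(ex$data$group)) == 2)
    valence_permutation_test(ex$data, seed = config$seed) else NULL

  if (!is.null(out_dir)) {
    log_stage(paste("writing outputs to", out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset_csv(ex$data, file.path(out_dir, "trials.csv"))
    if (!is.null(psy))
      write.csv(psy, file.path(out_dir, "psychometric_fits.csv"),
                row.names = FALSE)
    for (g in names(ests))
      write.csv(ests[[g]],
                file.path(out_dir, paste0("ddm_estimates_", g, ".csv")),
                row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed,
           exclusions = unclass(ex$report)[1:4],
           correlations = cors,
           permutation = perm),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  log_stage("done")
  list(data = ex$data, exclusions = ex$report, psychometric = psy,
       posteriors = posts, estimates = ests, judgment_biases = biases,
       correlations = cors, permutation = perm)
}
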