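#' Model specifications of the diffusion family
#'
#' Four nested specifications separate the two candidate mechanisms of
#' valence-dependent judgment:
#' \describe{
#'   \item{1}{valence independent: starting point fixed at 0.5, a single
#'     symmetric drift magnitude (`+v` on desirable-state trials, `-v` on
#'     undesirable-state trials);}
#'   \item{2}{valence-dependent starting point: `0 < z < 1` free, symmetric
#'     drift;}
#'   \item{3}{valence-dependent drift rate: `z = 0.5`, drift magnitude
#'     `b0 + b1 * desirability`;}
#'   \item{4}{both biases free.}
#' }
#' All specifications include the across-trial starting-point range `sz`.
#'
#' @param model_id Integer 1-4.
#' @return An object of class `ddm_model_spec` with fields `model_id`,
#'   `free_starting_point` and `valence_dependent_drift`.
#' @examples
#' build_model(4)
#' @export
build_model <- function(model_id) {
  if (length(model_id) != 1 || !model_id %in% 1:4)
    stop("`model_id` must be one of 1, 2, 3, 4")
  model_id <- as.integer(model_id)
  structure(list(model_id = model_id,
                 free_starting_point = model_id %in% c(2L, 4L),
                 valence_dependent_drift = model_id %in% c(3L, 4L)),
            class = "ddm_model_spec")
}

#' @export
print.ddm_model_spec <- function(x, ...) {
  lab <- c("valence independent", "valence-dependent starting point",
           "valence-dependent drift rate",
           "valence-dependent drift rate and starting point")
  cat(sprintf("Diffusion model %d: %s\n", x$model_id, lab[x$model_id]))
  cat(sprintf("  starting point: %s\n",
              if (x$free_starting_point) "0 < z < 1 (free)" else "z = 0.5"))
  cat(sprintf("  drift: %s\n",
              if (x$valence_dependent_drift)
                "v = b0 + b1 * desirability" else "symmetric v / -v"))
  invisible(x)
}

#' Drift-rate regression coefficients
#'
#' The valence-dependent drift magnitude is a linear function of the trial's
#' true-state desirability: `v = v_intercept + v_bias * desirability_code`,
#' with desirability coded 1 on desirable-state trials and 0 on
#' undesirable-state trials.  A positive `v_bias` means evidence toward the
#' desirable conclusion accumulates faster than evidence toward the
#' undesirable one.
#'
#' @param v_intercept Drift constant (log-RT scale).
#' @param v_bias Valence bias added on desirable-state trials.
#' @return An object of class `drift_regression`.
#' @export
drift_regression <- function(v_intercept, v_bias = 0) {
  if (!all(is.finite(c(v_intercept, v_bias))))
    stop("drift regression coefficients must be finite")
  structure(list(v_intercept = v_intercept, v_bias = v_bias),
            class = "drift_regression")
}

#' Evaluate the drift-rate regression
#'
#' @param reg A [drift_regression()] object.
#' @param desirability_code 0/1 vector: 1 on desirable-state trials.
#' @return Drift magnitude(s) `v_intercept + v_bias * desirability_code`.
#' @examples
#' drift_rate(drift_regression(0.46, 0.17), 1) # 0.63
#' @export
drift_rate <- function(reg, desirability_code) {
  stopifnot(inherits(reg, "drift_regression"))
  if (!all(desirability_code %in% c(0, 1)))
    stop("`desirability_code` must be 0 or 1")
  reg$v_intercept + reg$v_bias * desirability_code
}

#' Map trials to boundaries and signed drift
#'
#' Fixes the package's orientation convention: the upper boundary is the
#' desirable-state judgment and the lower boundary the undesirable-state
#' judgment, for every model.  The trial's drift magnitude (from the
#' symmetric `v` or the valence regression, depending on the specification)
#' points toward the correct boundary: positive (toward upper) on
#' desirable-state trials, negative on undesirable-state trials.
#'
#' @param spec A [build_model()] specification.
#' @param reg A [drift_regression()]; for models 1-2 only `v_intercept` is
#'   used as the symmetric drift magnitude.
#' @param desirability_code 0/1 vector of true-state desirability.
#' @return A data.frame with columns `desirability_code`, `upper_choice`
#'   (always `"desirable"`), `lower_choice` (always `"undesirable"`) and
#'   `drift` (signed, toward the upper boundary).
#' @export
map_boundaries <- function(spec, reg, desirability_code) {
  stopifnot(inherits(spec, "ddm_model_spec"))
  v <- effective_drift(spec, reg, desirability_code)
  data.frame(desirability_code = desirability_code,
             upper_choice = "desirable", lower_choice = "undesirable",
             drift = v, stringsAsFactors = FALSE)
}

#' Signed drift toward the upper (desirable-judgment) boundary
#'
#' @inheritParams map_boundaries
#' @return Numeric vector of signed drifts.
#' @export
effective_drift <- function(spec, reg, desirability_code) {
  stopifnot(inherits(spec, "ddm_model_spec"), inherits(reg, "drift_regression"))
  vmag <- if (spec$valence_dependent_drift)
    drift_rate(reg, desirability_code) else rep(reg$v_intercept,
                                                length(desirability_code))
  ifelse(desirability_code == 1, vmag, -vmag)
}

#' Group-level diffusion parameters with subject-level spreads
#'
#' Describes the hierarchical population a group of subjects is drawn from:
#' natural-scale group locations for each diffusion parameter plus
#' subject-level spreads on the sampling scales used by the hierarchical
#' model (log for the threshold, identity for non-decision time and the two
#' drift terms, logit for the starting point).  `start_range` (sz) is a
#' single group-level value shared by all subjects.
#'
#' @param threshold,nondecision,start,start_range Group locations on the
#'   natural scale; see [ddm_params()].
#' @param drift_intercept,drift_bias Group locations of the drift
#'   regression.
#' @param sd_log_threshold,sd_nondecision,sd_logit_start,sd_drift_intercept,sd_drift_bias
#'   Subject-level standard deviations on the sampling scales.
#' @return An object of class `ddm_group_params`.
#' @export
group_params <- function(threshold, nondecision, start = 0.5,
                         start_range = 0, drift_intercept = 0,
                         drift_bias = 0,
                         sd_log_threshold = 0.10, sd_nondecision = 0.10,
                         sd_logit_start = 0.25, sd_drift_intercept = 0.15,
                         sd_drift_bias = 0.10) {
  # validate the location parameters through the single-subject constructor
  ddm_params(threshold, nondecision, start, start_range, drift_intercept)
  sds <- c(sd_log_threshold, sd_nondecision, sd_logit_start,
           sd_drift_intercept, sd_drift_bias)
  if (!all(is.finite(sds)) || any(sds < 0))
    stop("subject-level spreads must be finite and non-negative")
  structure(list(threshold = threshold, nondecision = nondecision,
                 start = start, start_range = start_range,
                 drift_intercept = drift_intercept, drift_bias = drift_bias,
                 sd_log_threshold = sd_log_threshold,
                 sd_nondecision = sd_nondecision,
                 sd_logit_start = sd_logit_start,
                 sd_drift_intercept = sd_drift_intercept,
                 sd_drift_bias = sd_drift_bias),
            class = "ddm_group_params")
}

#' Reference group parameters for the factory task
#'
#' Group-level estimates of the winning valence-dependent model for the two
#' experimental groups of the incentivized factory task (control and
#' social-threat), used as the package's reference generating values for
#' simulation and recovery studies.  Subject-level spreads are the package
#' defaults of [group_params()].
#'
#' @param group `"control"` or `"threat"`.
#' @return A [group_params()] object.
#' @examples
#' factory_group_params("control")
#' @export
factory_group_params <- function(group = c("control", "threat")) {
  group <- match.arg(group)
  if (group == "control")
    group_params(threshold = 2.67, nondecision = 7.55, start = 0.48,
                 start_range = 0.18, drift_intercept = 0.46,
                 drift_bias = 0.17)
  else
    group_params(threshold = 2.47, nondecision = 7.49, start = 0.51,
                 start_range = 0.19, drift_intercept = 0.63,
                 drift_bias = -0.08)
}

#' Prior ranges for hierarchical estimation
#'
#' Flat priors over generous, physically sensible ranges on each sampling
#' scale, with a half-normal prior on the subject-level spreads.  The
#' ranges keep the sampler inside the region where the first-passage
#' density is well defined while assigning equal probability to all
#' plausible values.
#'
#' @param sigma_tau Scale of the half-normal prior on group spreads.
#' @param sz_max Upper bound of the flat prior on the starting-point range.
#' @return A list of ranges, one per sampling-scale parameter.
#' @export
default_priors <- function(sigma_tau = 0.5, sz_max = 0.6) {
  list(log_threshold = log(c(0.3, 6)),
       nondecision = c(0, 10),
       logit_start = qlogis(c(0.05, 0.95)),
       drift_intercept = c(-5, 5),
       drift_bias = c(-5, 5),
       sigma_tau = sigma_tau,
       sz_max = sz_max)
}
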