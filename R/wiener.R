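#' Diffusion parameters for the two-boundary Wiener process
#'
#' Bundles the parameters of a single diffusion process: boundary
#' separation, non-decision time, relative starting point, across-trial
#' starting-point range and drift rate.  The diffusion coefficient is fixed
#' at 1 and all quantities are on the log response-time scale (see
#' \link{valenceddm}).
#'
#' @param threshold Boundary separation \eqn{\alpha > 0}.
#' @param nondecision Non-decision time \eqn{t_0 \ge 0} (log-ms units).
#' @param start Relative starting point \eqn{z \in (0, 1)}; 0.5 is unbiased.
#' @param start_range Across-trial starting-point range \eqn{sz \ge 0}; on
#'   each trial the start is uniform on \eqn{z \pm sz/2}, which must stay
#'   inside (0, 1).
#' @param drift Drift rate \eqn{v} toward the upper boundary.
#' @return An object of class `ddm_params`.
#' @examples
#' ddm_params(threshold = 2.5, nondecision = 7.5, start = 0.5, drift = 0.5)
#' @export
ddm_params <- function(threshold, nondecision, start = 0.5, start_range = 0,
                       drift = 0) {
  stopifnot(is.numeric(threshold), is.numeric(nondecision), is.numeric(start),
            is.numeric(start_range), is.numeric(drift))
  if (!all(is.finite(c(threshold, nondecision, start, start_range, drift))))
    stop("all diffusion parameters must be finite")
  if (threshold <= 0) stop("`threshold` must be positive")
  if (nondecision < 0) stop("`nondecision` must be non-negative")
  if (start <= 0 || start >= 1) stop("`start` must lie strictly in (0, 1)")
  if (start_range < 0) stop("`start_range` must be non-negative")
  if (start - start_range / 2 <= 0 || start + start_range / 2 >= 1)
    stop("starting-point range z +/- sz/2 must stay inside (0, 1)")
  structure(list(threshold = threshold, nondecision = nondecision,
                 start = start, start_range = start_range, drift = drift,
                 noise = 1),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Wiener diffusion parameters (log-RT scale, sigma = 1)\n")
  cat(sprintf("  threshold a = %.4g, nondecision t0 = %.4g\n",
              x$threshold, x$nondecision))
  cat(sprintf("  start z = %.4g, start range sz = %.4g, drift v = %.4g\n",
              x$start, x$start_range, x$drift))
  invisible(x)
}

#' First-passage time density of the Wiener diffusion
#'
#' Defective density of absorption at one boundary at observed time `t`
#' (which includes the non-decision time: the decision time is
#' `t - nondecision`).  The density is zero at or before the non-decision
#' time, is non-negative everywhere, and integrates, jointly over both
#' boundaries and all times, to 1.  Computed from the standard small-time /
#' large-time series representation with truncation tolerance `eps`; when
#' `start_range > 0` the density is averaged over the uniform starting-point
#' range by 11-node Gauss-Legendre quadrature.
#'
#' @param t Vector of observed times (log-RT units); must be finite.
#' @param boundary `"upper"` or `"lower"`.
#' @param params A [ddm_params()] object.
#' @param eps Series truncation tolerance.
#' @return Vector of densities, one per element of `t`.
#' @examples
#' p <- ddm_params(2.5, 7.5, drift = 0.5)
#' wfpt_density(7.5 + c(0.1, 0.5, 1), "upper", p)
#' @export
wfpt_density <- function(t, boundary = c("upper", "lower"), params,
                         eps = 1e-7) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "ddm_params"))
  if (!all(is.finite(t))) stop("`t` must be finite")
  wfpt_density_cpp(t - params$nondecision, boundary == "upper",
                   params$threshold, params$drift, params$start,
                   params$start_range, eps)
}

# Closed-form upper-boundary absorption probability for sz = 0,
# numerically stable in the drift.
.choice_prob_point <- function(a, v, z) {
  if (abs(v) < 1e-10) return(z)
  num <- -expm1(-2 * v * a * z)
  den <- -expm1(-2 * v * a)
  if (is.finite(num) && is.finite(den) && den != 0) return(num / den)
  # very large negative drift: work with ratios of exponentials
  exp(-2 * v * a * z - log1p(-exp(pmin(-2 * v * a, 700))))
}

#' Probability of absorbing at the upper boundary
#'
#' For zero drift the probability equals the relative starting point `z`;
#' otherwise it is \eqn{(1 - e^{-2 v a z}) / (1 - e^{-2 v a})} with
#' diffusion coefficient 1.  When `start_range > 0` the probability is
#' averaged over the uniform starting-point range.
#'
#' @inheritParams wfpt_density
#' @return A single probability.
#' @examples
#' choice_probability(ddm_params(1, 0, start = 0.5, drift = 1)) # ~0.731
#' @export
choice_probability <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  a <- params$threshold; v <- params$drift
  z <- params$start; sz <- params$start_range
  if (sz <= 0) return(.choice_prob_point(a, v, z))
  nodes <- z + sz / 2 * .gl11$x
  sum(.gl11$w * vapply(nodes, function(w) .choice_prob_point(a, v, w), 0)) / 2
}

# 11-node Gauss-Legendre rule on [-1, 1] (weights sum to 2); mirrors the
# rule compiled into the likelihood code.
.gl11 <- list(
  x = c(-0.97822865814605620, -0.88706259976809454, -0.73015200557404891,
        -0.51909612920681214, -0.26954315595234446, 0,
        0.26954315595234490, 0.51909612920681159, 0.73015200557404913,
        0.88706259976809509, 0.97822865814605697),
  w = c(0.055668567116170103, 0.125580369464904557, 0.186290210927737010,
        0.233193764591989872, 0.262804544510246929, 0.272925086777901393,
        0.262804544510245319, 0.233193764591991148, 0.186290210927734484,
        0.125580369464904057, 0.055668567116173344))

#' Simulate first passages of the Wiener diffusion
#'
#' Euler-Maruyama path simulation with a Brownian-bridge correction for
#' crossings between grid points, used throughout the package as a
#' brute-force oracle for [wfpt_density()] and [choice_probability()].
#' When `start_range > 0` each path draws its start uniformly on
#' \eqn{z \pm sz/2}.  Uses R's random number generator, so results are
#' reproducible under [set.seed()].
#'
#' @inheritParams wfpt_density
#' @param n Number of paths.
#' @param dt Time step; must be positive.
#' @param t_max Censoring horizon (paths still running are assigned to the
#'   nearer boundary; practically unreachable at default settings).
#' @return A data.frame with columns `boundary` (`"upper"`/`"lower"`) and
#'   `decision_time` (time beyond the non-decision time, always positive).
#' @examples
#' set.seed(1)
#' fp <- simulate_first_passage(ddm_params(1, 0, drift = 1), n = 1000)
#' mean(fp$boundary == "upper")
#' @export
simulate_first_passage <- function(params, n = 1, dt = 1e-3, t_max = 200) {
  stopifnot(inherits(params, "ddm_params"))
  if (dt <= 0) stop("step size `dt` must be positive")
  sim <- simulate_fp_cpp(n, params$threshold, params$drift, params$start,
                         params$start_range, dt, t_max)
  data.frame(boundary = ifelse(sim$boundary == 1, "upper", "lower"),
             decision_time = sim$decision_time,
             stringsAsFactors = FALSE)
}

#' Trial log-likelihood under the Wiener diffusion
#'
#' Log of the first-passage density evaluated at the observed log response
#' time on the boundary corresponding to the observed choice.  Observations
#' at or before the non-decision time are impossible under the model and
#' return `-Inf` (no error is raised).
#'
#' @param log_rt Vector of observed log response times; must be finite.
#' @param choice `"upper"`/`"lower"` (recycled or one per observation).
#' @inheritParams wfpt_density
#' @return Vector of log-likelihoods.
#' @export
trial_loglik <- function(log_rt, choice, params, eps = 1e-7) {
  stopifnot(inherits(params, "ddm_params"))
  if (!all(is.finite(log_rt))) stop("`log_rt` must be finite")
  if (!all(choice %in% c("upper", "lower")))
    stop("`choice` must be \"upper\" or \"lower\"")
  if (length(choice) == 1) choice <- rep(choice, length(log_rt))
  d <- numeric(length(log_rt))
  for (b in c("upper", "lower")) {
    i <- choice == b
    if (any(i)) d[i] <- wfpt_density(log_rt[i], b, params, eps)
  }
  ifelse(d > 0, log(d), -Inf)
}
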