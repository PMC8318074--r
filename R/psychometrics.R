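#' Centered evidence strength of a trial
#'
#' The proportion of TV items among all items observed before the response,
#' centered at 0.5: it ranges from 0.5 when all samples were TVs to -0.5
#' when all were phones.
#'
#' @param n_tv_observed Number of TV items observed.
#' @param n_observed Total items observed (at least 1).
#' @return Centered proportion(s) in `[-0.5, 0.5]`.
#' @examples
#' center_evidence(6, 10) # 0.1
#' @export
center_evidence <- function(n_tv_observed, n_observed) {
  if (any(n_observed < 1)) stop("`n_observed` must be at least 1")
  if (any(n_tv_observed < 0 | n_tv_observed > n_observed))
    stop("`n_tv_observed` must lie between 0 and `n_observed`")
  n_tv_observed / n_observed - 0.5
}

.new_psychometric_fit <- function(beta0, beta1, ci_beta0, ci_beta1,
                                  condition, n, separation = FALSE) {
  if (is.finite(beta1) && beta1 <= 0)
    warning("fitted slope is not positive; task-consistent data should ",
            "yield beta1 > 0")
  structure(list(beta0 = beta0, beta1 = beta1, ci_beta0 = ci_beta0,
                 ci_beta1 = ci_beta1, condition = condition, n = n,
                 separation = separation),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("Psychometric fit (%s): beta0 = %.3f [%.3f, %.3f], beta1 = %.2f [%.2f, %.2f], n = %d\n",
              paste(unlist(x$condition), collapse = ", "), x$beta0,
              x$ci_beta0[1], x$ci_beta0[2], x$beta1, x$ci_beta1[1],
              x$ci_beta1[2], x$n))
  if (x$separation) cat("  (ridge-penalized fit: separation detected)\n")
  invisible(x)
}

#' Psychometric choice probability
#'
#' Evaluates \eqn{P(TV) = 1 / (1 + e^{-(\beta_1 x - \beta_0)})} at centered
#' evidence `x`.  Strictly increasing in `x` whenever `beta1 > 0` and
#' bounded in (0, 1).  Note the sign convention of the indifference
#' parameter: `P = 0.5` at `x = beta0 / beta1`.
#'
#' @param fit A `psychometric_fit` (or any list with `beta0`, `beta1`).
#' @param x Centered evidence value(s).
#' @return Probability of the TV judgment.
#' @examples
#' predict_psychometric(list(beta0 = 0.23, beta1 = 25.55), 0.23 / 25.55)
#' @export
predict_psychometric <- function(fit, x) {
  if (!all(is.finite(c(fit$beta0, fit$beta1)))) stop("fit must be finite")
  plogis(fit$beta1 * x - fit$beta0)
}

#' @export
predict.psychometric_fit <- function(object, x, ...) {
  predict_psychometric(object, x)
}

#' Indifference point of a psychometric fit
#'
#' The centered evidence level at which the TV judgment is made half the
#' time: `beta0 / beta1` under the package's logistic parameterization, so
#' that `predict_psychometric(fit, indifference_point(fit))` is exactly 0.5.
#'
#' @inheritParams predict_psychometric
#' @return A single evidence value.
#' @export
indifference_point <- function(fit) {
  if (fit$beta1 == 0) stop("indifference point undefined for beta1 = 0")
  fit$beta0 / fit$beta1
}

# TV-coded response from the valence-coded choice column
.tv_response <- function(data) {
  if (!"tv_desirable" %in% names(data))
    stop("dataset has no `tv_desirable` column; the TV coding of choices ",
         "cannot be reconstructed")
  (data$choice == "desirable") == data$tv_desirable
}

# pooled MLE of the logistic, with optional ridge penalty on both
# coefficients (used when separation is detected)
.fit_logistic <- function(x, y, ridge = 0) {
  if (ridge > 0) {
    nll <- function(b) {
      eta <- b[2] * x - b[1]
      -sum(y * eta - log1p(exp(eta))) + ridge * sum(b^2)
    }
    o <- optim(c(0, 1), nll, method = "BFGS")
    c(beta0 = o$par[1], beta1 = o$par[2])
  } else {
    f <- suppressWarnings(glm(y ~ x, family = binomial()))
    c(beta0 = -unname(coef(f)[1]), beta1 = unname(coef(f)[2]))
  }
}

.is_separated <- function(x, y, b) {
  if (length(unique(y)) < 2) return(TRUE)
  !all(is.finite(b)) || abs(b["beta1"]) > 1e3 || abs(b["beta0"]) > 1e3
}

#' Fit the psychometric function to one condition
#'
#' Pooled maximum-likelihood logistic fit of the TV judgment against the
#' centered proportion of TV items observed, for the subjects of one
#' condition (a group crossed with whether the TV factory was the
#' desirable one), with subject-resampling (cluster) bootstrap confidence
#' intervals.  Complete separation (including responses constant across
#' trials) falls back to a small ridge penalty, with a warning.
#'
#' @param data A `behavioral_dataset` carrying a `tv_desirable` column.
#' @param group Optional group label to subset on.
#' @param tv_desirable Optional logical to subset on subjects for whom the
#'   TV factory was desirable (`TRUE`) or undesirable (`FALSE`).
#' @param n_boot Bootstrap replicates for the 95\% confidence intervals.
#' @param seed Seed for the bootstrap resampling.
#' @param ridge Ridge penalty used on the separation fallback.
#' @return A `psychometric_fit` with `beta0`, `beta1` and their intervals.
#' @export
fit_psychometric <- function(data, group = NULL, tv_desirable = NULL,
                             n_boot = 200, seed = 1, ridge = 1e-3) {
  d <- as.data.frame(data)
  if (!is.null(group)) d <- d[d$group == group, ]
  if (!is.null(tv_desirable)) {
    if (!"tv_desirable" %in% names(d))
      stop("dataset has no `tv_desirable` column")
    d <- d[d$tv_desirable == tv_desirable, ]
  }
  if (!nrow(d)) stop("no trials in the requested condition")
  if (any(d$n_observed < 1)) stop("`n_observed` must be at least 1")
  x <- center_evidence(d$n_tv_observed, d$n_observed)
  if (length(unique(x)) < 2)
    stop("need at least 2 distinct evidence values to fit a slope")
  y <- as.numeric(.tv_response(d))

  b <- .fit_logistic(x, y)
  sep <- .is_separated(x, y, b)
  if (sep) {
    warning("complete separation detected; using a ridge-penalized fit")
    b <- .fit_logistic(x, y, ridge = ridge)
  }

  if (n_boot == 0)
    return(.new_psychometric_fit(unname(b["beta0"]), unname(b["beta1"]),
                                 ci_beta0 = c(NA_real_, NA_real_),
                                 ci_beta1 = c(NA_real_, NA_real_),
                                 condition = list(group = group,
                                                  tv_desirable = tv_desirable),
                                 n = nrow(d), separation = sep))
  set.seed(seed)
  ids <- unique(d$subject_id)
  boot <- matrix(NA_real_, n_boot, 2)
  for (i in seq_len(n_boot)) {
    take <- ids[sample.int(length(ids), length(ids), replace = TRUE)]
    idx <- unlist(lapply(take, function(s) which(d$subject_id == s)))
    bb <- .fit_logistic(x[idx], y[idx], ridge = if (sep) ridge else 0)
    if (!sep && .is_separated(x[idx], y[idx], bb))
      bb <- .fit_logistic(x[idx], y[idx], ridge = ridge)
    boot[i, ] <- bb
  }
  ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  .new_psychometric_fit(unname(b["beta0"]), unname(b["beta1"]),
                        ci_beta0 = unname(ci[, 1]),
                        ci_beta1 = unname(ci[, 2]),
                        condition = list(group = group,
                                         tv_desirable = tv_desirable),
                        n = nrow(d), separation = sep)
}

#' Psychometric fits for all group-by-desirability conditions
#'
#' @param data A `behavioral_dataset` with `group` and `tv_desirable`.
#' @inheritParams fit_psychometric
#' @return A data.frame with one row per condition: group, tv_desirable,
#'   beta0, beta1 and their 95\% bootstrap intervals, and n (trials).
#' @export
fit_psychometric_conditions <- function(data, n_boot = 200, seed = 1) {
  grid <- expand.grid(group = unique(data$group),
                      tv_desirable = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- data$group == grid$group[i] &
      data$tv_desirable == grid$tv_desirable[i]
    if (!any(sub)) return(NULL) # condition absent from this dataset
    f <- fit_psychometric(data, group = grid$group[i],
                          tv_desirable = grid$tv_desirable[i],
                          n_boot = n_boot, seed = seed)
    data.frame(group = grid$group[i], tv_desirable = grid$tv_desirable[i],
               beta0 = f$beta0, beta0_lo = f$ci_beta0[1],
               beta0_hi = f$ci_beta0[2], beta1 = f$beta1,
               beta1_lo = f$ci_beta1[1], beta1_hi = f$ci_beta1[2],
               n = f$n)
  })
  do.call(rbind, rows)
}
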