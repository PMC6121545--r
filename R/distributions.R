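#' Fit a beta distribution by method of moments
#'
#' Solves for the shape parameters of a beta distribution whose mean and
#' standard error match the supplied values. This is the standard way to turn
#' a published probability with a standard error into a sampling distribution
#' for probabilistic sensitivity analysis.
#'
#' @param mean Mean probability, strictly between 0 and 1.
#' @param se Standard error on the same scale; must satisfy
#'   `se^2 < mean * (1 - mean)` (the variance bound for a beta distribution).
#' @return A named list with elements `alpha` and `beta`.
#' @examples
#' beta_params_from_moments(0.18, 0.0070)
#' @export
beta_params_from_moments <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1, length(se) == 1)
  if (!(mean > 0 && mean < 1)) {
    stop("`mean` must lie strictly between 0 and 1, got ", mean, call. = FALSE)
  }
  if (se <= 0) stop("`se` must be > 0 (a point mass is not a beta distribution)", call. = FALSE)
  v_max <- mean * (1 - mean)
  if (se^2 >= v_max) {
    stop(sprintf(
      "infeasible variance: se^2 = %.6g must be < mean*(1-mean) = %.6g",
      se^2, v_max
    ), call. = FALSE)
  }
  nu <- v_max / se^2 - 1 # alpha + beta
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Fit a gamma distribution by method of moments
#'
#' @param mean Mean cost (or any positive quantity).
#' @param se Standard error, positive.
#' @return A named list with elements `shape` and `scale` such that
#'   `shape * scale == mean` and `shape * scale^2 == se^2`.
#' @examples
#' gamma_params_from_moments(23229, 5807)
#' @export
gamma_params_from_moments <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1, length(se) == 1)
  if (mean <= 0 || se <= 0) {
    stop("`mean` and `se` must both be > 0 for a gamma fit", call. = FALSE)
  }
  list(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Fit a log-normal distribution from a 95% confidence interval
#'
#' Used for relative risks reported as a point estimate with a 95% CI. The
#' log-scale standard deviation is taken from the CI width,
#' `sigma = (log(ci_high) - log(ci_low)) / (2 * 1.96)`, and the log-scale mean
#' from the CI midpoint, so the fitted distribution's central 95% interval
#' reproduces the printed range exactly. A degenerate interval
#' (`ci_low == ci_high`) yields `sigma = 0`, a point mass.
#'
#' @param mean Published point estimate (retained for validation only).
#' @param ci_low,ci_high Bounds of the 95% confidence interval, positive.
#' @return A named list with elements `mu` and `sigma` on the log scale.
#' @examples
#' lognormal_params_from_ci(1.14, 1.08, 1.20)
#' @export
lognormal_params_from_ci <- function(mean, ci_low, ci_high) {
  stopifnot(is.numeric(ci_low), is.numeric(ci_high))
  if (ci_low <= 0 || ci_high <= 0) {
    stop("confidence bounds must be positive for a log-normal fit", call. = FALSE)
  }
  if (ci_low > ci_high) stop("`ci_low` must be <= `ci_high`", call. = FALSE)
  if (!missing(mean) && !is.null(mean)) {
    if (!(ci_low <= mean && mean <= ci_high)) {
      stop("`mean` must lie inside [ci_low, ci_high]", call. = FALSE)
    }
  }
  list(
    mu = (log(ci_low) + log(ci_high)) / 2,
    sigma = (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975))
  )
}

#' Convert an odds ratio to a relative risk
#'
#' Applies the standard conversion `RR = OR / (1 - p0 + p0 * OR)` where `p0`
#' is the outcome risk in the unexposed group. For `OR > 1` the result always
#' lies strictly between 1 and the odds ratio.
#'
#' @param odds_ratio Odds ratio, positive.
#' @param baseline_risk Outcome probability among the unexposed, in (0, 1).
#' @return The relative risk (scalar, vectorised over inputs).
#' @examples
#' or_to_rr(2.0, 0.18)
#' @export
or_to_rr <- function(odds_ratio, baseline_risk) {
  if (any(odds_ratio <= 0)) stop("`odds_ratio` must be > 0", call. = FALSE)
  if (any(baseline_risk <= 0 | baseline_risk >= 1)) {
    stop("`baseline_risk` must lie strictly between 0 and 1", call. = FALSE)
  }
  odds_ratio / (1 - baseline_risk + baseline_risk * odds_ratio)
}
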