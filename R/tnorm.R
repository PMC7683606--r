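# Truncated-normal draws via the inverse-CDF transform. Used throughout the
# cohort generator so that marginal event-day distributions are *exactly*
# the configured truncated normals (the hierarchical individual/cycle
# structure enters through the uniform quantile, not the marginal).

#' Truncated normal quantile function
#'
#' @param p probabilities in `[0, 1]`.
#' @param mean,sd location and scale of the parent normal (`sd > 0`).
#' @param lower,upper truncation bounds (`lower < upper`).
#' @return Quantiles of the normal distribution truncated to
#'   `[lower, upper]`.
#' @export
qtnorm <- function(p, mean, sd, lower, upper) {
  if (!is.finite(sd) || sd <= 0) stop("truncated normal requires sd > 0", call. = FALSE)
  if (lower >= upper) stop("truncated normal requires lower < upper", call. = FALSE)
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  q <- qnorm(plo + p * (phi - plo), mean, sd)
  pmin(pmax(q, lower), upper)
}

#' Truncated normal random draws
#'
#' @param n number of draws.
#' @inheritParams qtnorm
#' @export
rtnorm <- function(n, mean, sd, lower, upper) {
  qtnorm(runif(n), mean, sd, lower, upper)
}

# Mean and SD of a truncated normal by numerical integration. Kept for
# moment checks against large simulated samples; deliberately naive
# (quadrature over the closed-form density) so it is independent of the
# inverse-CDF sampling path.
tnorm_moments_numint <- function(mean, sd, lower, upper) {
  z <- pnorm(upper, mean, sd) - pnorm(lower, mean, sd)
  dens <- function(x) dnorm(x, mean, sd) / z
  m1 <- integrate(function(x) x * dens(x), lower, upper, rel.tol = 1e-10)$value
  m2 <- integrate(function(x) x^2 * dens(x), lower, upper, rel.tol = 1e-10)$value
  list(mean = m1, sd = sqrt(m2 - m1^2))
}
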