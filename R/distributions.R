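# Probability kernels used by the generative model, plus their derivatives
# with respect to the variate (needed for reparameterized gradients).

#' Half-Cauchy(scale) log density for x > 0
#' @param x positive numeric vector.
#' @param scale positive scale.
#' @keywords internal
#' @noRd
.dhalfcauchy_log <- function(x, scale = 1) {
  log(2) - log(pi) - log(scale) - log1p((x / scale)^2)
}

.dhalfcauchy_grad <- function(x, scale = 1) {
  -2 * x / (scale^2 + x^2)
}

#' Inverse-Gamma(shape, rate) log density
#' @keywords internal
#' @noRd
.dinvgamma_log <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

.dinvgamma_grad <- function(x, shape, rate) {
  -(shape + 1) / x + rate / x^2
}

# location-0 Student-t with scale
.dstudent_log <- function(x, df, sd) {
  stats::dt(x / sd, df = df, log = TRUE) - log(sd)
}

.dstudent_grad <- function(x, df, sd) {
  -(df + 1) * x / (df * sd^2 + x^2)
}

.dbeta_log <- function(x, a, b) stats::dbeta(x, a, b, log = TRUE)

.dbeta_grad <- function(x, a, b) (a - 1) / x - (b - 1) / (1 - x)

#' Gamma-Poisson (negative binomial) log probability mass
#'
#' Mean/dispersion parameterization: a Poisson whose rate is Gamma-distributed
#' with mean \code{mu} and concentration \code{1/alpha}, so that
#' \eqn{Var = \mu + \alpha \mu^2}. The limit \code{alpha -> 0} recovers a
#' Poisson with mean \code{mu}; \code{alpha = 0} is evaluated exactly as
#' Poisson.
#'
#' @param x non-negative integer counts (vector or matrix).
#' @param mu positive means, recycled against \code{x}.
#' @param alpha non-negative dispersions, recycled against \code{x}.
#' @return log pmf values, same shape as \code{x}.
#' @examples
#' gamma_poisson_logpmf(0, 1, 1)   # log(0.5)
#' gamma_poisson_logpmf(3, 2, 0)   # dpois(3, 2, log = TRUE)
#' @export
gamma_poisson_logpmf <- function(x, mu, alpha) {
  .assert(all(x >= 0) && all(x == round(x)), "counts must be non-negative integers")
  .assert(all(mu > 0), "mu must be positive")
  .assert(all(alpha >= 0), "alpha must be non-negative")
  out <- x * 0
  pois <- alpha == 0
  if (any(pois)) {
    out[pois] <- stats::dpois(x[pois], if (length(mu) == 1) mu else mu[pois], log = TRUE)
  }
  if (any(!pois)) {
    a <- if (length(alpha) == 1) alpha else alpha[!pois]
    m <- if (length(mu) == 1) mu else mu[!pois]
    xx <- x[!pois]
    size <- 1 / a
    out[!pois] <- stats::dnbinom(xx, size = size, mu = m, log = TRUE)
  }
  dim(out) <- dim(x)
  out
}

# d/dmu and d/dalpha of the NB log pmf (alpha > 0 assumed)
.gp_grad_mu <- function(x, mu, alpha) {
  x / mu - (1 + alpha * x) / (1 + alpha * mu)
}

.gp_grad_alpha <- function(x, mu, alpha) {
  ia <- 1 / alpha
  (-ia^2) * (digamma(x + ia) - digamma(ia)) +
    ia^2 * log1p(alpha * mu) - ia * mu / (1 + alpha * mu) +
    x / alpha - x * mu / (1 + alpha * mu)
}

#' Matern-3/2 covariance matrix over a time grid
#'
#' \eqn{\kappa(t,t') = \sigma^2 (1 + \sqrt3 |t-t'|/l) \exp(-\sqrt3 |t-t'|/l)},
#' plus \code{jitter} on the diagonal for numerical positive definiteness.
#'
#' @param times numeric vector of time points.
#' @param sigma_sq output variance (scalar, positive).
#' @param length_scale kernel length scale, default 1.
#' @param jitter diagonal jitter, default 1e-6.
#' @return symmetric positive-definite matrix of size \code{length(times)}.
#' @examples
#' matern32_covariance(c(0, 1), 1)  # off-diagonal (1 + sqrt(3)) * exp(-sqrt(3))
#' @export
matern32_covariance <- function(times, sigma_sq, length_scale = 1, jitter = 1e-6) {
  .assert(all(is.finite(times)), "times must be finite")
  .assert(length_scale > 0, "length_scale must be positive")
  .assert(sigma_sq > 0, "sigma_sq must be positive")
  d <- abs(outer(times, times, "-")) * sqrt(3) / length_scale
  K <- sigma_sq * (1 + d) * exp(-d)
  K + diag(jitter, length(times))
}
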