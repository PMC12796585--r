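# Sinh-arcsinh (SHASH) distribution, Jones-Pewsey form as used in the GAMLSS
# literature. With z = (y - mu)/sigma and w = tau*asinh(z) - nu:
#   F(y)  = Phi(sinh(w))
#   f(y)  = tau*cosh(w) / (sigma*sqrt(2*pi)*sqrt(1+z^2)) * exp(-sinh(w)^2/2)
#   Q(p)  = mu + sigma*sinh((asinh(qnorm(p)) + nu)/tau)
# nu = 0, tau = 1 recovers Normal(mu, sigma); nu > 0 skews right; tau < 1
# gives heavier tails.

check_shash <- function(mu, sigma, nu, tau) {
  if (any(!is.finite(mu)) || any(!is.finite(sigma)) ||
      any(!is.finite(nu)) || any(!is.finite(tau))) {
    abort("SHASH parameters must be finite")
  }
  if (any(sigma <= 0)) abort("`sigma` must be positive")
  if (any(tau <= 0)) abort("`tau` must be positive")
  invisible(TRUE)
}

#' The sinh-arcsinh (SHASH) distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the four-parameter sinh-arcsinh distribution with location `mu`,
#' scale `sigma`, skewness `nu` and tail weight `tau`. `nu = 0, tau = 1`
#' is exactly `Normal(mu, sigma)`.
#'
#' @param x,q,y numeric vector of values.
#' @param p numeric vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param mu location (in observation units).
#' @param sigma scale, `> 0`.
#' @param nu skewness; positive values skew right.
#' @param tau tail weight, `> 0`; values below 1 thicken the tails.
#' @param log,log.p if `TRUE` return log density / log probability.
#' @param lower.tail if `TRUE` (default) probabilities are `P(Y <= y)`.
#' @return `dshash` the density, `pshash` the CDF, `qshash` the quantile
#'   function, `rshash` a vector of `n` draws.
#' @examples
#' pshash(0, mu = 0, sigma = 1, nu = 0, tau = 1) # 0.5, the normal limit
#' qshash(0.975, mu = 0, sigma = 1, nu = 0, tau = 1)
#' @name shash
NULL

#' @rdname shash
#' @export
dshash <- function(x, mu = 0, sigma = 1, nu = 0, tau = 1, log = FALSE) {
  check_shash(mu, sigma, nu, tau)
  z <- (x - mu) / sigma
  w <- tau * asinh(z) - nu
  r <- sinh(w)
  ll <- log(tau) + log(cosh(w)) - log(sigma) - 0.5 * log(2 * pi) -
    0.5 * log1p(z^2) - 0.5 * r^2
  if (log) ll else exp(ll)
}

#' @rdname shash
#' @export
pshash <- function(q, mu = 0, sigma = 1, nu = 0, tau = 1,
                   lower.tail = TRUE, log.p = FALSE) {
  if (any(is.na(q))) abort("`q` must not contain missing values")
  check_shash(mu, sigma, nu, tau)
  r <- sinh(tau * asinh((q - mu) / sigma) - nu)
  pnorm(r, lower.tail = lower.tail, log.p = log.p)
}

#' @rdname shash
#' @export
qshash <- function(p, mu = 0, sigma = 1, nu = 0, tau = 1) {
  check_shash(mu, sigma, nu, tau)
  if (any(p <= 0 | p >= 1)) abort("`p` must lie strictly within (0, 1)")
  mu + sigma * sinh((asinh(qnorm(p)) + nu) / tau)
}

#' @rdname shash
#' @export
rshash <- function(n, mu = 0, sigma = 1, nu = 0, tau = 1) {
  check_shash(mu, sigma, nu, tau)
  u <- rnorm(n)
  mu + sigma * sinh((asinh(u) + nu) / tau)
}
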