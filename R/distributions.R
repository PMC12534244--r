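#' Gamma shape and rate from mean and standard deviation
#'
#' Re-parameterises a Gamma distribution by its mean `mu` and standard
#' deviation `sigma`: rate `tau = mu / sigma^2`, shape `zeta = mu * tau`.
#' `Gamma(zeta, tau)` then has mean `mu` and SD `sigma`, so priors can be
#' placed directly on interpretable quantities instead of shape/rate.
#'
#' @param mu Mean, `> 0`. Vectorised.
#' @param sigma Standard deviation, `> 0`.
#' @return A list with elements `shape` and `rate`.
#' @export
gamma_shape_rate <- function(mu, sigma) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("`mu` must be positive")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("`sigma` must be positive")
  rate <- mu / sigma^2
  list(shape = mu * rate, rate = rate)
}

#' Beta shape parameters from mean and standard deviation
#'
#' Re-parameterises a Beta distribution via an individual-level mean `mu` and
#' SD `sigma`: the scale parameter is `phi = (1 - mu) * mu / sigma^2 - 1`, and
#' the shapes are `kappa = mu * phi`, `gamma = (1 - mu) * phi`. Validity
#' requires `sigma^2 < mu (1 - mu)` (otherwise `phi <= 0`), which is exactly
#' the support restriction behind the Uniform(0, sqrt(mu(1-mu))) prior on the
#' Beta SD.
#'
#' @param mu Mean in `(0, 1)`. Vectorised.
#' @param sigma Standard deviation with `0 < sigma^2 < mu (1 - mu)`.
#' @return A list with elements `kappa`, `gamma` and `phi`.
#' @export
beta_shapes <- function(mu, sigma) {
  if (any(!is.finite(mu)) || any(mu <= 0 | mu >= 1)) {
    stop("`mu` must be strictly inside (0, 1)")
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("`sigma` must be positive")
  if (any(sigma^2 >= mu * (1 - mu))) {
    stop("`sigma^2` must be below mu*(1-mu): SD bound for a Beta distribution violated")
  }
  phi <- (1 - mu) * mu / sigma^2 - 1
  list(kappa = mu * phi, gamma = (1 - mu) * phi, phi = phi)
}

#' Original-scale moments of a Log-Normal distribution
#'
#' For `exp(Normal(nu, delta^2))`, returns the mean and SD on the original
#' scale: `mu = exp(nu + delta^2 / 2)` and
#' `sigma = sqrt((exp(delta^2) - 1) exp(2 nu + delta^2))`. Both are strictly
#' increasing in `delta` for fixed `nu` — the mechanism by which a Uniform
#' prior with a generous upper bound on the log-scale SD implies explosively
#' large cost means and SDs on the currency scale.
#'
#' @param nu Log-scale mean. Vectorised.
#' @param delta Log-scale standard deviation, `>= 0`.
#' @return A list with elements `mu` and `sigma` (original scale).
#' @export
lognormal_moments <- function(nu, delta) {
  if (any(!is.finite(nu))) stop("`nu` must be finite")
  if (any(!is.finite(delta)) || any(delta < 0)) stop("`delta` must be >= 0")
  mu <- exp(nu + delta^2 / 2)
  sigma <- sqrt((exp(delta^2) - 1) * exp(2 * nu + delta^2))
  list(mu = mu, sigma = sigma)
}

#' Log-scale parameters of a Log-Normal from original-scale moments
#'
#' Inverse of [lognormal_moments()]: given a target mean `mu > 0` and SD
#' `sigma > 0` on the original scale, returns `(nu, delta)` such that
#' `exp(Normal(nu, delta^2))` has those moments.
#'
#' @param mu Original-scale mean, `> 0`. Vectorised.
#' @param sigma Original-scale SD, `> 0`.
#' @return A list with elements `nu` and `delta`.
#' @export
lognormal_params <- function(mu, sigma) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("`mu` must be positive")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("`sigma` must be positive")
  delta2 <- log(1 + sigma^2 / mu^2)
  list(nu = log(mu) - delta2 / 2, delta = sqrt(delta2))
}

#' Original-scale SD implied by a Uniform prior on the log-scale SD
#'
#' Tabulates, for a fixed log-scale mean `nu`, the original-scale mean and SD
#' implied by log-scale SD values on a grid over `(0, upper)` — the support
#' of a Uniform(0, upper) prior. Useful for judging whether a candidate upper
#' bound on the log-cost SD still corresponds to plausible currency-scale
#' dispersion.
#'
#' @param nu Log-scale mean (e.g. `log` of a typical cost).
#' @param upper Upper bound of the Uniform prior on the log-scale SD.
#' @param n_grid Number of grid points (default 50).
#' @return A data.frame with columns `delta`, `implied_mean`, `implied_sd`.
#' @export
implied_sd_grid <- function(nu, upper, n_grid = 50) {
  stopifnot(is.finite(nu), is.finite(upper), upper > 0, n_grid >= 2)
  delta <- seq(upper / n_grid, upper, length.out = n_grid)
  m <- lognormal_moments(nu, delta)
  data.frame(delta = delta, implied_mean = m$mu, implied_sd = m$sigma)
}
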