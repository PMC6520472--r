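#' Spatial log-normal flux distribution parameters
#'
#' At a fixed time after fertilisation, plot-to-plot N2O fluxes are modelled
#' as log-normal with location `mu_log` and scale `sigma_log` (the mean and
#' standard deviation of the log-transformed flux). The arithmetic-scale mean
#' `mu = exp(mu_log + 0.5 sigma_log^2)` is derived and stored alongside.
#'
#' @param mu_log location of the log-flux
#' @param sigma_log scale of the log-flux, >= 0
#' @return an object of class `spatial_params`
#' @export
spatial_params <- function(mu_log, sigma_log) {
  stopifnot(is.numeric(mu_log), length(mu_log) == 1L, is.finite(mu_log),
            is.numeric(sigma_log), length(sigma_log) == 1L, is.finite(sigma_log))
  if (sigma_log < 0) stop("sigma_log must be >= 0")
  structure(list(mu_log = mu_log, sigma_log = sigma_log,
                 mu = lognormal_mean(mu_log, sigma_log)),
            class = "spatial_params")
}

#' Log-normal probability density of a spatial flux sample
#'
#' Density of a positive flux under the spatial log-normal model. Non-positive
#' fluxes have zero density (the distribution's support is (0, Inf)); this is
#' returned as 0 (or -Inf on the log scale), not raised as an error, because
#' background-adjusted field fluxes can legitimately be <= 0.
#'
#' @param flux flux value(s), nmol N2O m^-2 s^-1 (or any consistent unit)
#' @param params a [spatial_params()] object
#' @param log logical, return log-density
#' @export
spatial_pdf <- function(flux, params, log = FALSE) {
  stopifnot(inherits(params, "spatial_params"), is.numeric(flux))
  out <- ifelse(flux > 0,
                stats::dlnorm(pmax(flux, .Machine$double.xmin),
                              meanlog = params$mu_log, sdlog = params$sigma_log,
                              log = log),
                if (log) -Inf else 0)
  out
}

#' Arithmetic mean of a log-normal distribution
#'
#' @param mu_log location parameter
#' @param sigma_log scale parameter, >= 0
#' @return exp(mu_log + 0.5 * sigma_log^2)
#' @export
lognormal_mean <- function(mu_log, sigma_log) {
  stopifnot(is.numeric(mu_log), is.numeric(sigma_log))
  if (any(sigma_log < 0)) stop("sigma_log must be >= 0")
  exp(mu_log + 0.5 * sigma_log^2)
}

#' Temporal flux model parameters
#'
#' Parameter vector of the peak-and-decay emission model: following
#' fertilisation the spatial-mean N2O flux rises to a peak and decays, a shape
#' described by a log-normal density in time scaled by the total emitted N.
#'
#' * `delta` (log days): natural log of the delay between application and peak
#'   flux (location of the temporal log-normal).
#' * `k` (> 0): decay-scale (breadth) of the temporal log-normal.
#' * `omega` (0 <= omega < 1 in practice): fraction of applied N emitted as
#'   N2O-N as t -> Inf.
#' * `sigma_log` (>= 0): spatial log-scale of plot-to-plot variability.
#' * `n_in` (kg N ha^-1): fertiliser nitrogen input.
#'
#' @param delta,k,omega,sigma_log,n_in see Details
#' @return an object of class `temporal_params`
#' @export
temporal_params <- function(delta, k, omega, sigma_log, n_in) {
  vals <- c(delta = delta, k = k, omega = omega,
            sigma_log = sigma_log, n_in = n_in)
  if (length(vals) != 5L || any(!is.finite(vals)))
    stop("all temporal parameters must be finite scalars")
  if (k <= 0) stop("k must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  if (sigma_log < 0) stop("sigma_log must be >= 0")
  if (n_in < 0) stop("n_in must be >= 0")
  structure(as.list(vals), class = "temporal_params")
}

#' @export
print.temporal_params <- function(x, ...) {
  cat(sprintf(
    "temporal_params: delta=%.4g (peak ~%.3g d), k=%.4g, omega=%.4g, sigma_log=%.4g, n_in=%.4g kg N/ha\n",
    x$delta, exp(x$delta - x$k^2), x$k, x$omega, x$sigma_log, x$n_in))
  invisible(x)
}

#' Spatial-mean emission rate at time t
#'
#' The expected (spatial-mean) emission rate t days after fertilisation:
#' `mu_t = dlnorm(t; delta, k) * n_in * omega`, in kg N ha^-1 day^-1.
#' Integrates to `n_in * omega` over (0, Inf), tends to 0 as t -> 0+ and
#' t -> Inf, and peaks at t = exp(delta - k^2).
#'
#' @param t days since application, > 0 (vectorised)
#' @param params a [temporal_params()] object
#' @export
temporal_mean <- function(t, params) {
  stopifnot(inherits(params, "temporal_params"), is.numeric(t))
  if (any(t <= 0)) stop("t must be > 0")
  stats::dlnorm(t, meanlog = params$delta, sdlog = params$k) *
    params$n_in * params$omega
}

#' Time-indexed location parameter of the spatial distribution
#'
#' Location `mu_log_t = log(mu_t) - 0.5 * sigma_log^2` such that a log-normal
#' with scale `sigma_log` has arithmetic mean exactly `mu_t`. When `mu_t = 0`
#' (e.g. omega = 0) the value is -Inf, interpreted as a point mass at zero.
#'
#' @inheritParams temporal_mean
#' @export
mu_log_at_t <- function(t, params) {
  mu_t <- temporal_mean(t, params)
  ifelse(mu_t > 0, log(mu_t) - 0.5 * params$sigma_log^2, -Inf)
}

#' Closed-form cumulative flux
#'
#' Cumulative emission from application (t = 0) to day t:
#' `F_cum(t) = pnorm((log(t) - delta) / k) * n_in * omega` (kg N ha^-1) — the
#' log-normal CDF scaled by total emitted N. Monotone non-decreasing, 0 at
#' t = 0, asymptote `n_in * omega`.
#'
#' @param t days since application, >= 0 (vectorised)
#' @param params a [temporal_params()] object
#' @export
cumulative_flux <- function(t, params) {
  stopifnot(inherits(params, "temporal_params"), is.numeric(t))
  if (any(t < 0)) stop("t must be >= 0")
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- stats::pnorm((log(t[pos]) - params$delta) / params$k) *
    params$n_in * params$omega
  out
}

#' Log-likelihood of chamber flux observations under the space-time model
#'
#' Each observation (plot p, day t) of measured flux F is log-normal with
#' scale `sigma_log` and location set so that its mean is the temporal-model
#' mean plus the constant background rate B estimated from control plots:
#' `mu_log_t = log(mu_t + B) - 0.5 sigma_log^2`. The background is a mean
#' offset in the model, not a per-observation subtraction: control-plot
#' scatter around B would otherwise turn tail-of-event observations into
#' apparent outliers and destroy the fit. Measured fluxes at or below a small
#' positivity floor (chamber regressions can go negative) are treated as
#' left-censored at the floor and contribute the log-CDF there, keeping such
#' observations in the likelihood without breaking the log-normal support.
#'
#' @param observations data.frame with columns `day` (> 0) and
#'   `flux_nmol_m2_s`
#' @param params a [temporal_params()] object
#' @param background_rate constant background emission rate added to the
#'   model mean, kg N ha^-1 day^-1
#' @param floor_nmol left-censoring floor on the nmol m^-2 s^-1 scale
#' @return scalar log-likelihood
#' @export
log_likelihood <- function(observations, params, background_rate = 0,
                           floor_nmol = 1e-4) {
  stopifnot(inherits(params, "temporal_params"))
  obs <- validate_flux_obs(observations, require_labels = FALSE)
  if (nrow(obs) == 0L) stop("empty observation set")
  if (any(obs$day <= 0)) stop("observations must have day > 0")
  ll_terms(y_nmol = obs$flux_nmol_m2_s, t_days = obs$day, params = params,
           background_rate = background_rate, floor_nmol = floor_nmol)
}

# Core likelihood kernel shared with the MCMC sampler. Works on the
# kg N ha^-1 day^-1 scale; `y_nmol` is the measured chamber flux and
# `background_rate` a constant offset on the model mean.
ll_terms <- function(y_nmol, t_days, params, background_rate = 0,
                     floor_nmol = 1e-4) {
  eps <- convert_flux_units(floor_nmol)
  y <- convert_flux_units(y_nmol)
  mu_t <- stats::dlnorm(t_days, meanlog = params$delta, sdlog = params$k) *
    params$n_in * params$omega + background_rate
  cens <- y <= eps
  if (params$sigma_log == 0) {
    # degenerate spatial distribution: point mass at mu_t
    ok <- (cens & mu_t <= eps) | (!cens & abs(y - mu_t) < 1e-12)
    return(if (all(ok)) 0 else -Inf)
  }
  mu_log <- ifelse(mu_t > 0, log(mu_t) - 0.5 * params$sigma_log^2, -Inf)
  ll <- numeric(length(y))
  zero_mean <- !is.finite(mu_log)
  # mu_t = 0: point mass at zero -> censored obs certain, positive impossible
  ll[zero_mean & cens] <- 0
  ll[zero_mean & !cens] <- -Inf
  fin <- !zero_mean
  ll[fin & cens] <- stats::plnorm(eps, mu_log[fin & cens], params$sigma_log,
                                  log.p = TRUE)
  idx <- fin & !cens
  ll[idx] <- stats::dlnorm(y[idx], mu_log[idx], params$sigma_log, log = TRUE)
  sum(ll)
}
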