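#' Static chamber geometry
#'
#' Either give `volume` and `area` directly, or a cylindrical chamber's
#' `diameter` and `height` (metres), from which V = pi r^2 h and A = pi r^2.
#' Only the ratio V/A (the effective headspace height) enters the flux
#' calculation.
#'
#' @param volume chamber volume, m^3
#' @param area enclosed ground area, m^2
#' @param diameter,height cylinder dimensions, m (alternative parameterisation)
#' @export
chamber_geometry <- function(volume = NULL, area = NULL,
                             diameter = NULL, height = NULL) {
  if (is.null(volume) || is.null(area)) {
    if (is.null(diameter) || is.null(height))
      stop("give either volume+area or diameter+height")
    area <- pi * (diameter / 2)^2
    volume <- area * height
  }
  stopifnot(is.numeric(volume), is.numeric(area))
  if (volume <= 0 || area <= 0) stop("volume and area must be > 0")
  structure(list(volume = volume, area = area), class = "chamber_geometry")
}

#' Air state inside the chamber headspace
#'
#' Molar density of air, either supplied directly or derived from the ideal
#' gas law rho = P / (R T) with R = 8.314 J mol^-1 K^-1. Defaults correspond
#' to 20 degC and standard pressure (rho ~= 41.57 mol m^-3).
#'
#' @param rho molar density, mol m^-3 (overrides temperature/pressure)
#' @param temperature air temperature, K
#' @param pressure air pressure, Pa
#' @export
air_state <- function(rho = NULL, temperature = 293.15, pressure = 101325) {
  if (is.null(rho)) {
    stopifnot(temperature > 0, pressure > 0)
    rho <- pressure / (8.314 * temperature)
  }
  if (!is.numeric(rho) || rho <= 0) stop("rho must be > 0")
  structure(list(rho = rho), class = "air_state")
}

#' Chamber headspace concentration series
#'
#' @param times seconds since chamber closure, strictly increasing, >= 3
#'   samples (2 allowed but flagged downstream)
#' @param concentrations N2O mole fraction, nmol mol^-1, non-negative
#' @export
gas_sample_series <- function(times, concentrations) {
  stopifnot(is.numeric(times), is.numeric(concentrations))
  if (length(times) != length(concentrations))
    stop("times and concentrations must have equal length")
  if (length(times) < 2L) stop("need at least 2 samples (3 recommended)")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  structure(list(times = as.numeric(times),
                 concentrations = as.numeric(concentrations)),
            class = "gas_sample_series")
}

#' Headspace accumulation slope dC/dt by linear regression
#'
#' Ordinary least-squares slope of concentration on time, with standard error
#' from the residual variance. With only two samples the slope degrades to the
#' two-point difference quotient; the SE is then undefined (NA) and the fit is
#' flagged `"two-point"`. R^2 is recorded in the qc fields but no filter is
#' applied: poor fits are the caller's decision.
#'
#' @param series a [gas_sample_series()]
#' @return list with `slope` (nmol mol^-1 s^-1), `se`, `r_squared`, `n`,
#'   `qc_flag`
#' @export
fit_dcdt <- function(series) {
  stopifnot(inherits(series, "gas_sample_series"))
  t <- series$times; C <- series$concentrations
  n <- length(t)
  if (n == 2L) {
    return(list(slope = diff(C) / diff(t), se = NA_real_,
                r_squared = NA_real_, n = 2L, qc_flag = "two-point"))
  }
  fit <- stats::lm.fit(cbind(1, t), C)
  slope <- unname(fit$coefficients[2L])
  rss <- sum(fit$residuals^2)
  sxx <- sum((t - mean(t))^2)
  se <- sqrt(rss / (n - 2L) / sxx)
  tss <- sum((C - mean(C))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  flag <- if (!is.na(r2) && r2 < 0.9) "low-r2" else "ok"
  list(slope = slope, se = se, r_squared = r2, n = n, qc_flag = flag)
}

#' Chamber flux from a concentration series
#'
#' F = dC/dt * rho * V / A, giving nmol N2O m^-2 s^-1. Negative fluxes are
#' retained (soil uptake of N2O is physically possible and small negative
#' fluxes occur in field data); they carry the regression qc flag.
#'
#' @param series a [gas_sample_series()]
#' @param chamber a [chamber_geometry()]
#' @param air an [air_state()]
#' @param full logical; if TRUE return a list with flux, slope fit and qc
#' @export
#' @examples
#' s <- gas_sample_series(c(0, 1200, 2400, 3600), c(330, 340, 350, 360))
#' compute_flux(s, chamber_geometry(diameter = 0.38, height = 0.22), air_state())
compute_flux <- function(series, chamber, air, full = FALSE) {
  stopifnot(inherits(chamber, "chamber_geometry"), inherits(air, "air_state"))
  fit <- fit_dcdt(series)
  flux <- fit$slope * air$rho * chamber$volume / chamber$area
  if (full) c(list(flux = flux), fit) else flux
}
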