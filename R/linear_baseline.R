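#' Spatial-mean flux series for trapezoidal integration
#'
#' Collapses plot-level observations to the per-day spatial mean (the "mean of
#' n plots" that cumulative-flux tables are built from).
#'
#' @param observations data.frame with columns `day` and `flux_nmol_m2_s`
#'   (plot-level rows)
#' @return data.frame `days`, `mean_flux`, `n_plots`, ordered by day, class
#'   `mean_flux_series`
#' @export
mean_flux_series <- function(observations) {
  obs <- validate_flux_obs(observations, require_labels = FALSE)
  if (nrow(obs) == 0L) stop("empty observation set")
  agg <- stats::aggregate(obs$flux_nmol_m2_s, by = list(day = obs$day),
                          FUN = function(x) c(mean(x), length(x)))
  out <- data.frame(days = agg$day,
                    mean_flux = agg$x[, 1L],
                    n_plots = as.integer(agg$x[, 2L]))
  out <- out[order(out$days), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mean_flux_series", "data.frame")
  out
}

#' Trapezoidal (linear-interpolation) cumulative flux
#'
#' Piecewise-linear integral of the spatial-mean flux from day 0 to
#' `window_days`, converted to kg N ha^-1. This is the standard comparator
#' for model-based cumulative estimates.
#'
#' Edge handling, since the first sample is rarely at day 0 and the last not
#' always at the window end, is configurable:
#' \describe{
#'   \item{"default"}{flux held at the first measured value over the half day
#'     preceding the first sample, zero before that; held at the last measured
#'     value from the last sample to the window end.}
#'   \item{"zero"}{zero outside the measured range.}
#'   \item{"hold"}{first value held back to day 0 and last value held to the
#'     window end.}
#' }
#'
#' @param series a [mean_flux_series()], or any data.frame with `days` and
#'   `mean_flux` columns
#' @param window_days integration window length (days)
#' @param edge edge-handling rule, see Details
#' @return cumulative flux, kg N ha^-1
#' @export
trapezoid_cumulative <- function(series, window_days = 30,
                                 edge = c("default", "zero", "hold")) {
  edge <- match.arg(edge)
  if (is.data.frame(series) && !inherits(series, "mean_flux_series")) {
    stopifnot(all(c("days", "mean_flux") %in% names(series)))
  }
  d <- series$days
  f <- series$mean_flux
  if (length(d) == 0L) stop("empty series")
  if (any(diff(d) <= 0)) stop("days must be strictly increasing")
  keep <- d <= window_days
  if (!any(keep)) stop("no measurement within the integration window")
  d <- d[keep]; f <- f[keep]

  # interior: plain trapezoid between measurement days (nmol-day units)
  area <- if (length(d) > 1L) sum(diff(d) * (utils::head(f, -1) + utils::tail(f, -1)) / 2) else 0

  # leading edge
  lead <- switch(edge,
    default = f[1L] * (d[1L] - max(0, d[1L] - 0.5)),
    zero    = 0,
    hold    = f[1L] * d[1L])
  # trailing edge
  trail <- switch(edge,
    default = ,
    hold    = f[length(f)] * (window_days - d[length(d)]),
    zero    = 0)

  convert_flux_units(1) * (area + lead + trail)
}

#' Per-plot trapezoidal cumulative fluxes
#'
#' Integrates each plot's own series and returns one total per plot; the mean
#' of these equals [trapezoid_cumulative()] of the spatial mean when sampling
#' is complete and balanced across plots.
#'
#' @inheritParams trapezoid_cumulative
#' @param observations plot-level flux data.frame with `plot`, `day`,
#'   `flux_nmol_m2_s`
#' @return named numeric vector of kg N ha^-1 per plot
#' @export
trapezoid_by_plot <- function(observations, window_days = 30,
                              edge = c("default", "zero", "hold")) {
  edge <- match.arg(edge)
  obs <- validate_flux_obs(observations, require_labels = FALSE)
  if (!"plot" %in% names(obs)) stop("observations need a 'plot' column")
  vapply(split(obs, obs$plot), function(p) {
    p <- p[order(p$day), ]
    trapezoid_cumulative(data.frame(days = p$day, mean_flux = p$flux_nmol_m2_s),
                         window_days = window_days, edge = edge)
  }, numeric(1))
}
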