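#' Plot a flux time series with the posterior mean curve and credible ribbon
#'
#' Base-graphics diagnostic plot of one event-treatment: plot-level fluxes
#' over days since application, the posterior-mean temporal curve, the 95%
#' credible ribbon of the mean flux, and the background rate as a dashed
#' line. All rates shown in nmol N2O m^-2 s^-1.
#'
#' @param observations plot-level flux data.frame (`day`, `flux_nmol_m2_s`)
#' @param chains a `posterior_chains` object from [sample_posterior()]
#' @param n_curve number of grid points for the fitted curve
#' @param ... passed to [graphics::plot()]
#' @export
plot_flux_fit <- function(observations, chains, n_curve = 121, ...) {
  obs <- validate_flux_obs(observations, require_labels = FALSE)
  m <- draw_matrix(chains)
  tt <- seq(0.25, chains$window_days, length.out = n_curve)
  curves <- vapply(seq_len(nrow(m)), function(i) {
    stats::dlnorm(tt, m[i, "delta"], m[i, "k"]) * chains$n_in * m[i, "omega"]
  }, numeric(length(tt)))
  curves <- convert_rate_to_flux(curves)
  lo <- apply(curves, 1L, stats::quantile, probs = 0.025)
  hi <- apply(curves, 1L, stats::quantile, probs = 0.975)
  mid <- rowMeans(curves)
  bg <- convert_rate_to_flux(chains$background_rate)
  ylim <- range(0, obs$flux_nmol_m2_s, hi + bg)
  graphics::plot(obs$day, obs$flux_nmol_m2_s, pch = 16,
                 col = grDevices::adjustcolor("black", 0.6),
                 xlab = "days since application",
                 ylab = expression(paste("flux (nmol ", N[2], "O ",
                                         m^-2, " ", s^-1, ")")),
                 ylim = ylim, ...)
  graphics::polygon(c(tt, rev(tt)), c(lo + bg, rev(hi + bg)), border = NA,
                    col = grDevices::adjustcolor("steelblue", 0.3))
  graphics::lines(tt, mid + bg, col = "steelblue", lwd = 2)
  graphics::abline(h = bg, col = "firebrick", lty = 2)
  invisible(list(t = tt, mean = mid, ci_low = lo, ci_high = hi))
}

#' Plot pooled posterior EF densities per treatment
#'
#' Overlays the kernel densities of pooled EF draw sets (one per treatment),
#' the cross-experiment probability distribution of the emission factor.
#'
#' @param pooled named list of [pooled_posterior_pdf()] outputs
#' @param xlim x-axis range (EF, %)
#' @param ... passed to [graphics::plot()]
#' @export
plot_pooled_efs <- function(pooled, xlim = NULL, ...) {
  stopifnot(length(pooled) >= 1L, !is.null(names(pooled)))
  dens <- lapply(pooled, `[[`, "density")
  if (is.null(xlim)) xlim <- range(vapply(dens, function(d) range(d$x),
                                          numeric(2)))
  ymax <- max(vapply(dens, function(d) max(d$y), numeric(1)))
  cols <- grDevices::hcl.colors(length(dens), "Dark 3")
  graphics::plot(NA, xlim = xlim, ylim = c(0, ymax),
                 xlab = "emission factor (% of applied N)",
                 ylab = "posterior density", ...)
  for (i in seq_along(dens))
    graphics::lines(dens[[i]], col = cols[i], lwd = 2)
  graphics::legend("topright", legend = names(pooled), col = cols, lwd = 2,
                   bty = "n")
  invisible(NULL)
}
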