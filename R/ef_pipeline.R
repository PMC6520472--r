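#' Cumulative background flux from control plots
#'
#' Trapezoidal integral of the per-day spatial mean of the control-plot
#' fluxes over the event window — the quantity subtracted from every
#' treatment's cumulative flux before an emission factor is computed.
#'
#' @param control_obs data.frame of control-plot observations with `day` and
#'   `flux_nmol_m2_s`
#' @param window_days integration window, days
#' @param edge edge-handling rule, see [trapezoid_cumulative()]
#' @return kg N ha^-1
#' @export
background_cumulative <- function(control_obs, window_days = 30,
                                  edge = "default") {
  if (is.null(control_obs) || nrow(control_obs) == 0L)
    stop("no control-plot observations: cannot estimate the background flux")
  trapezoid_cumulative(mean_flux_series(control_obs),
                       window_days = window_days, edge = edge)
}

#' Mean background emission rate from control plots
#'
#' Time-mean of the per-day control-plot spatial means, converted to
#' kg N ha^-1 day^-1 — the constant offset the likelihood subtracts.
#'
#' @inheritParams background_cumulative
#' @export
background_rate <- function(control_obs) {
  if (is.null(control_obs) || nrow(control_obs) == 0L)
    stop("no control-plot observations: cannot estimate the background flux")
  s <- mean_flux_series(control_obs)
  convert_flux_units(mean(s$mean_flux))
}

#' Emission factor
#'
#' EF = 100 * (cumulative - background) / n_in, the percentage of applied N
#' emitted as N2O-N over the window after background subtraction. May be
#' negative when treatment plots emitted less than controls.
#'
#' @param cumulative treatment cumulative flux, kg N ha^-1
#' @param background background cumulative flux, kg N ha^-1
#' @param n_in applied N, kg N ha^-1, > 0
#' @return EF in percent (vectorised)
#' @export
emission_factor <- function(cumulative, background, n_in) {
  if (any(n_in <= 0)) stop("n_in must be > 0")
  100 * (cumulative - background) / n_in
}

#' Aggregate per-event emission factors
#'
#' Arithmetic mean, n-1 sample SD and median of EFs per group (typically per
#' fertiliser treatment), plus the overall median pooling all values. A group
#' with a single value gets `sd = NA` (flagged, not an error).
#'
#' @param efs numeric vector of per-event EFs (%)
#' @param by grouping factor/character vector, same length as `efs`
#' @return list with `by_group` (data.frame: group, n, mean, sd, median) and
#'   `overall_median`
#' @export
aggregate_efs <- function(efs, by) {
  stopifnot(is.numeric(efs), length(efs) == length(by))
  if (length(efs) == 0L) stop("empty EF set")
  if (anyNA(efs)) stop("EFs must not contain NA")
  groups <- split(efs, by)
  if (any(vapply(groups, length, integer(1)) == 0L)) stop("empty group")
  by_group <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               median = stats::median(x))
  }))
  rownames(by_group) <- NULL
  list(by_group = by_group, overall_median = stats::median(efs))
}

#' Compare Bayesian and linear-interpolation emission factors
#'
#' Ordinary least-squares regression of the Bayesian EFs on the linear EFs
#' (slope, intercept, Pearson R^2) plus the through-origin slope
#' `sum(x*y)/sum(x^2)`. Both slopes are reported because published
#' method-comparison slopes do not always state whether an intercept was
#' fitted.
#'
#' @param linear_ef,bayes_ef paired EF vectors, >= 3 pairs
#' @return list with `slope`, `intercept`, `r_squared`, `slope_origin`, `n`
#' @export
compare_methods <- function(linear_ef, bayes_ef) {
  stopifnot(is.numeric(linear_ef), is.numeric(bayes_ef),
            length(linear_ef) == length(bayes_ef))
  if (length(linear_ef) < 3L) stop("need at least 3 pairs")
  if (stats::var(linear_ef) == 0 || stats::var(bayes_ef) == 0)
    stop("degenerate variance: EFs are constant")
  fit <- stats::lm.fit(cbind(1, linear_ef), bayes_ef)
  r2 <- stats::cor(linear_ef, bayes_ef)^2
  list(slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       r_squared = r2,
       slope_origin = sum(linear_ef * bayes_ef) / sum(linear_ef^2),
       n = length(linear_ef))
}

#' Pool posterior EF draws across events
#'
#' Equal-weight pooling of per-event posterior EF draw sets for one
#' treatment: each event contributes the same number of draws (subsampled
#' deterministically by thinning if lengths differ), so the pooled set is the
#' mixture distribution across events. Returns the pooled draws and a kernel
#' density estimate for plotting.
#'
#' @param chains_list list of `posterior_chains` objects (one per event), or
#'   a list of numeric EF draw vectors
#' @return list with `draws` (pooled numeric vector), `density` (a
#'   [stats::density()] object), `n_events`
#' @export
pooled_posterior_pdf <- function(chains_list) {
  if (length(chains_list) == 0L) stop("empty chains list")
  draw_sets <- lapply(chains_list, function(x) {
    if (inherits(x, "posterior_chains")) ef_draws(x) else as.numeric(x)
  })
  if (any(vapply(draw_sets, length, integer(1)) == 0L))
    stop("empty draw set")
  n_min <- min(vapply(draw_sets, length, integer(1)))
  pooled <- unlist(lapply(draw_sets, function(d) {
    if (length(d) == n_min) d
    else d[round(seq(1L, length(d), length.out = n_min))]  # even thinning
  }), use.names = FALSE)
  list(draws = pooled, density = stats::density(pooled),
       n_events = length(draw_sets))
}

#' Probability that one treatment's EF exceeds another's
#'
#' For pooled posterior draw sets A and B treated as independent, computes
#' P(A > B) exactly over the empirical distributions (the expected value of
#' comparing randomly paired independent draws; ties count 1/2). Implemented
#' by ranking, so it is deterministic and needs no pairing RNG.
#'
#' @param draws_a,draws_b numeric draw vectors
#' @export
prob_ef_greater <- function(draws_a, draws_b) {
  stopifnot(is.numeric(draws_a), is.numeric(draws_b),
            length(draws_a) > 0L, length(draws_b) > 0L)
  n_a <- length(draws_a); n_b <- length(draws_b)
  r <- rank(c(draws_a, draws_b), ties.method = "average")
  # Mann-Whitney U for sample A = sum of A ranks - n_a(n_a+1)/2 = #(a > b) + ties/2
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u / (n_a * n_b)
}

#' Analyse one fertilisation event
#'
#' Full per-event pipeline: estimate the background from control plots,
#' compute the trapezoidal cumulative flux and the posterior cumulative flux
#' for each treatment, subtract the background, and derive emission factors
#' by both methods. One output row per treatment mirrors the standard
#' cumulative-flux reporting table: background, linear cumulative, linear
#' minus background, Bayesian cumulative (posterior mean) with 95% credible
#' interval, Bayesian minus background, and both EFs.
#'
#' @param observations plot-level flux data.frame (`site`, `event`,
#'   `treatment`, `plot`, `day`, `flux_nmol_m2_s`); control plots labelled
#'   `control_label`
#' @param n_in applied N for this event, kg N ha^-1
#' @param window_days event window, days
#' @param priors a [prior_spec()]
#' @param config an [mcmc_config()]
#' @param edge trapezoid edge rule
#' @param control_label treatment label identifying control plots
#' @param keep_chains logical, attach the `posterior_chains` per treatment
#' @return list with `results` (data.frame, one row per treatment) and,
#'   if requested, `chains` (named list)
#' @export
analyse_event <- function(observations, n_in, window_days = 30,
                          priors = prior_spec(), config = mcmc_config(),
                          edge = "default", control_label = "control",
                          keep_chains = TRUE) {
  obs <- validate_flux_obs(observations, require_labels = TRUE)
  ctrl <- obs[obs$treatment == control_label, , drop = FALSE]
  bg_cum <- background_cumulative(ctrl, window_days, edge)
  bg_rate <- background_rate(ctrl)
  treatments <- setdiff(unique(obs$treatment), control_label)
  if (length(treatments) == 0L) stop("no treatment observations")

  chains_out <- list()
  rows <- lapply(treatments, function(tr) {
    tobs <- obs[obs$treatment == tr, , drop = FALSE]
    lin <- trapezoid_cumulative(mean_flux_series(tobs), window_days, edge)
    ch <- sample_posterior(tobs, n_in = n_in, background_rate = bg_rate,
                           priors = priors, config = config,
                           window_days = window_days,
                           background_cumulative = bg_cum)
    if (keep_chains) chains_out[[tr]] <<- ch
    ps <- posterior_cumulative(ch, window_days)
    data.frame(
      site = tobs$site[1L], event = tobs$event[1L], treatment = tr,
      n_in_kg_ha = n_in,
      background_cum_kg_ha = bg_cum,
      linear_cum_kg_ha = lin,
      linear_minus_background_kg_ha = lin - bg_cum,
      bayes_cum_kg_ha = ps$mean,
      bayes_ci_low_kg_ha = ps$ci_low,
      bayes_ci_high_kg_ha = ps$ci_high,
      bayes_minus_background_kg_ha = ps$mean - bg_cum,
      linear_ef_pct = emission_factor(lin, bg_cum, n_in),
      bayes_ef_pct = emission_factor(ps$mean, bg_cum, n_in))
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  out <- list(results = results)
  if (keep_chains) out$chains <- chains_out
  out
}

#' Analyse a multi-event campaign
#'
#' Runs [analyse_event()] for every (site, event) present in the observation
#' table, looking up each event's N input in `events`.
#'
#' @param observations plot-level flux table for all events
#' @param events event metadata data.frame with columns `site`, `event`,
#'   `n_in_kg_ha`
#' @inheritParams analyse_event
#' @return list with `results` (stacked EventResult rows) and `chains`
#'   (named `site.event.treatment`)
#' @export
analyse_campaign <- function(observations, events, window_days = 30,
                             priors = prior_spec(), config = mcmc_config(),
                             edge = "default", control_label = "control",
                             keep_chains = FALSE) {
  obs <- validate_flux_obs(observations, require_labels = TRUE)
  need <- c("site", "event", "n_in_kg_ha")
  if (!all(need %in% names(events)))
    stop("events table must have columns: ", paste(need, collapse = ", "))
  keys <- unique(obs[, c("site", "event")])
  all_res <- list(); all_chains <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- obs$site == keys$site[i] & obs$event == keys$event[i]
    ev <- events[events$site == keys$site[i] & events$event == keys$event[i], ]
    if (nrow(ev) != 1L)
      stop(sprintf("events table must have exactly one row for %s event %s",
                   keys$site[i], keys$event[i]))
    res <- analyse_event(obs[sel, ], n_in = ev$n_in_kg_ha,
                         window_days = window_days, priors = priors,
                         config = config, edge = edge,
                         control_label = control_label,
                         keep_chains = keep_chains)
    all_res[[i]] <- res$results
    if (keep_chains)
      for (tr in names(res$chains))
        all_chains[[paste(keys$site[i], keys$event[i], tr, sep = ".")]] <-
          res$chains[[tr]]
  }
  out <- list(results = do.call(rbind, all_res))
  if (keep_chains) out$chains <- all_chains
  out
}

#' Internal-consistency check of an event-result table
#'
#' Verifies, within a tolerance, the identities every results row must
#' satisfy: minus-background columns equal cumulative minus background, EFs
#' equal 100 * (cumulative - background) / n_in, and the credible interval
#' brackets the Bayesian point estimate.
#'
#' @param results an EventResult-shaped data.frame
#' @param tol absolute tolerance (use ~0.015 for tables rounded to 2 dp)
#' @return TRUE invisibly, or an error describing the violated invariant
#' @export
check_event_results <- function(results, tol = 1e-8) {
  with(results, {
    chk <- function(ok, what) if (!all(ok)) stop("invariant violated: ", what)
    chk(abs(linear_minus_background_kg_ha -
              (linear_cum_kg_ha - background_cum_kg_ha)) <= tol,
        "linear minus background")
    chk(abs(bayes_minus_background_kg_ha -
              (bayes_cum_kg_ha - background_cum_kg_ha)) <= tol,
        "bayes minus background")
    chk(abs(linear_ef_pct -
              100 * (linear_cum_kg_ha - background_cum_kg_ha) / n_in_kg_ha)
        <= tol, "linear EF")
    chk(abs(bayes_ef_pct -
              100 * (bayes_cum_kg_ha - background_cum_kg_ha) / n_in_kg_ha)
        <= tol, "bayes EF")
    chk(bayes_ci_low_kg_ha <= bayes_cum_kg_ha + tol &
          bayes_cum_kg_ha <= bayes_ci_high_kg_ha + tol,
        "credible interval brackets the point estimate")
  })
  invisible(TRUE)
}

#' Round-half-up to a number of decimals
#'
#' Presentation rounding for report tables (R's `round()` rounds half to
#' even, which does not match how field tables are typically printed).
#'
#' @param x numeric
#' @param digits decimals
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
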