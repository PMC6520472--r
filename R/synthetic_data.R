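#' Ground-truth specification for a synthetic fertilisation event
#'
#' Holds the generative parameters of one event: the temporal pulse
#' (`delta`, `k`, `omega`, `n_in`), the spatial scatter (`sigma_log`) and a
#' log-normal background flux common to all plots (`background_mu`, the mean
#' on the natural scale in nmol N2O m^-2 s^-1, and `background_sigma_log`).
#' The default background mean of 0.4 nmol m^-2 s^-1 matches typical control
#' plots on fertilised grassland.
#'
#' @param delta log-days to peak flux
#' @param k temporal decay-scale, > 0
#' @param omega emitted fraction of applied N, in [0, 1)
#' @param sigma_log spatial log-scale, >= 0
#' @param n_in applied N, kg N ha^-1
#' @param background_mu mean background flux, nmol N2O m^-2 s^-1, >= 0
#' @param background_sigma_log spatial log-scale of the background, >= 0
#' @export
truth_spec <- function(delta, k, omega, sigma_log, n_in,
                       background_mu = 0.4, background_sigma_log = 0.8) {
  vals <- c(delta, k, omega, sigma_log, n_in, background_mu,
            background_sigma_log)
  if (any(!is.finite(vals))) stop("all truth parameters must be finite")
  if (k <= 0) stop("k must be > 0")
  if (omega < 0 || omega >= 1) stop("omega must be in [0, 1)")
  if (sigma_log < 0 || background_sigma_log < 0)
    stop("log-scales must be >= 0")
  if (n_in < 0) stop("n_in must be >= 0")
  if (background_mu < 0) stop("background_mu must be >= 0")
  structure(list(delta = delta, k = k, omega = omega, sigma_log = sigma_log,
                 n_in = n_in, background_mu = background_mu,
                 background_sigma_log = background_sigma_log),
            class = "truth_spec")
}

#' @rdname truth_spec
#' @param x a `truth_spec`
#' @export
as_temporal_params <- function(x) {
  stopifnot(inherits(x, "truth_spec"))
  temporal_params(delta = x$delta, k = x$k, omega = x$omega,
                  sigma_log = x$sigma_log, n_in = x$n_in)
}

#' Measurement schedule of a chamber campaign
#'
#' @param measurement_days strictly increasing days since application, all in
#'   (0, window_days]
#' @param window_days event window length, default 30
#' @export
sampling_schedule <- function(measurement_days, window_days = 30) {
  d <- as.numeric(measurement_days)
  if (length(d) == 0L) stop("empty schedule")
  if (any(diff(d) <= 0)) stop("measurement days must be strictly increasing")
  if (any(d <= 0) || any(d > window_days))
    stop("measurement days must lie in (0, window_days]")
  structure(list(measurement_days = d, window_days = window_days),
            class = "sampling_schedule")
}

#' @rdname sampling_schedule
#' @description `schedule_daily_then_alternate()` is the manual-chamber
#'   schedule used at the intensively sampled sites: daily for two weeks after
#'   fertilisation, then every second day to the window end.
#'   `schedule_weekly_taper()` is the lower-frequency schedule: three visits a
#'   week for two weeks, two a week for two weeks, then weekly.
#' @param window_days event window length
#' @export
schedule_daily_then_alternate <- function(window_days = 30) {
  sampling_schedule(c(1:14, seq(16, window_days, by = 2)), window_days)
}

#' @rdname sampling_schedule
#' @export
schedule_weekly_taper <- function(window_days = 30) {
  d <- c(1, 3, 5, 8, 10, 12, 15, 18, 22, 25, 29)
  sampling_schedule(d[d <= window_days], window_days)
}

#' Plot layout of a fertilisation event
#'
#' Default mirrors a typical replicated trial: four treatment plots per
#' fertiliser plus four unfertilised control plots.
#'
#' @param n_treatment_plots plots per treatment, >= 1
#' @param n_control_plots control plots, >= 1
#' @param treatments character vector of treatment labels
#' @export
campaign_layout <- function(n_treatment_plots = 4, n_control_plots = 4,
                            treatments = "AN") {
  stopifnot(n_treatment_plots >= 1, n_control_plots >= 1,
            is.character(treatments), length(treatments) >= 1)
  if ("control" %in% treatments) stop("'control' is reserved for control plots")
  structure(list(n_treatment_plots = as.integer(n_treatment_plots),
                 n_control_plots = as.integer(n_control_plots),
                 treatments = treatments),
            class = "campaign_layout")
}

# one lognormal draw vector with arithmetic mean `mean` and log-scale `sdlog`;
# mean 0 => all zeros
rlnorm_mean <- function(n, mean, sdlog) {
  if (mean <= 0) return(numeric(n))
  if (sdlog == 0) return(rep(mean, n))
  stats::rlnorm(n, meanlog = log(mean) - 0.5 * sdlog^2, sdlog = sdlog)
}

#' Simulate one fertilisation event
#'
#' Draws plot-level chamber fluxes with the statistical structure the analysis
#' assumes: at day t each treatment plot's flux is an independent log-normal
#' pulse draw (mean = the temporal model's spatial mean at t, converted to
#' nmol m^-2 s^-1) plus an independent log-normal background draw; control
#' plots draw background only. Draws are independent across plots and days —
#' the model has no plot-persistence term, so neither does the generator.
#'
#' @param truth a [truth_spec()], or a named list of one `truth_spec` per
#'   treatment in `layout`
#' @param schedule a [sampling_schedule()]
#' @param layout a [campaign_layout()]
#' @param seed integer RNG seed; identical inputs + seed give identical output
#' @param site,event labels stamped on the output rows
#' @return data.frame with columns site, event, treatment, plot, day,
#'   flux_nmol_m2_s (control plots have treatment "control")
#' @export
simulate_event <- function(truth, schedule, layout, seed,
                           site = "SYN", event = 1L) {
  stopifnot(inherits(schedule, "sampling_schedule"),
            inherits(layout, "campaign_layout"))
  truths <- if (inherits(truth, "truth_spec")) {
    stats::setNames(rep(list(truth), length(layout$treatments)),
                    layout$treatments)
  } else {
    if (!all(layout$treatments %in% names(truth)))
      stop("truth list must name every treatment in the layout")
    lapply(truth[layout$treatments], function(x) {
      stopifnot(inherits(x, "truth_spec")); x })
  }
  set.seed(as.integer(seed))
  days <- schedule$measurement_days
  rows <- list()
  for (tr in layout$treatments) {
    th <- truths[[tr]]
    pars <- as_temporal_params(th)
    for (d in days) {
      mu_flux <- convert_rate_to_flux(temporal_mean(d, pars))
      pulse <- rlnorm_mean(layout$n_treatment_plots, mu_flux, th$sigma_log)
      bg <- rlnorm_mean(layout$n_treatment_plots, th$background_mu,
                        th$background_sigma_log)
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, event = event, treatment = tr,
        plot = paste0(tr, seq_len(layout$n_treatment_plots)),
        day = d, flux_nmol_m2_s = pulse + bg)
    }
  }
  bg_truth <- truths[[1L]]
  for (d in days) {
    bg <- rlnorm_mean(layout$n_control_plots, bg_truth$background_mu,
                      bg_truth$background_sigma_log)
    rows[[length(rows) + 1L]] <- data.frame(
      site = site, event = event, treatment = "control",
      plot = paste0("C", seq_len(layout$n_control_plots)),
      day = d, flux_nmol_m2_s = bg)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a chamber concentration series for a known flux
#'
#' Inverse of the chamber flux equation, for round-trip testing of
#' [compute_flux()]: concentrations rise linearly at rate flux * A / (rho * V)
#' from a baseline `c0`, with optional iid Gaussian analyser noise.
#'
#' @param flux soil flux, nmol N2O m^-2 s^-1
#' @param chamber a [chamber_geometry()]
#' @param air an [air_state()]
#' @param sample_times seconds since closure, increasing, >= 3 points
#' @param noise_sd Gaussian noise SD, nmol mol^-1 (0 = exact line)
#' @param c0 ambient mole fraction at closure, nmol mol^-1
#' @param seed optional RNG seed
#' @return a [gas_sample_series()]
#' @export
simulate_concentration_series <- function(flux, chamber, air, sample_times,
                                          noise_sd = 0, c0 = 330,
                                          seed = NULL) {
  stopifnot(inherits(chamber, "chamber_geometry"), inherits(air, "air_state"))
  if (length(sample_times) < 3L) stop("need at least 3 sample times")
  if (any(diff(sample_times) <= 0)) stop("sample times must be increasing")
  if (!is.null(seed)) set.seed(as.integer(seed))
  slope <- flux * chamber$area / (air$rho * chamber$volume)
  conc <- c0 + slope * sample_times
  if (noise_sd > 0) conc <- conc + stats::rnorm(length(conc), 0, noise_sd)
  gas_sample_series(sample_times, pmax(conc, 0))
}

#' Site presets for the synthetic campaign generator
#'
#' Bundles a realistic chamber geometry, sampling schedule, N application and
#' per-treatment ground truth for four grassland trial archetypes:
#' \describe{
#'   \item{EB, UJ}{cylindrical manual chambers (38 cm diameter, 22 cm height),
#'     daily sampling for two weeks then alternate days; 70 kg N ha^-1.}
#'   \item{HF, NW}{box chambers (50 x 50 cm, ~17.5 cm effective headspace),
#'     tapering 3x/2x/1x-weekly schedule; 90 kg N ha^-1.}
#' }
#' Treatment truths encode the pattern seen across UK grassland trials:
#' ammonium nitrate (AN) emitting ~0.6% of applied N, urea (Ur) and
#' inhibitor-treated urea (UI) roughly half that.
#'
#' @param name one of "EB", "HF", "NW", "UJ"
#' @return list with elements `site`, `truths`, `schedule`, `layout`,
#'   `chamber`, `n_in`
#' @export
site_preset <- function(name = c("EB", "HF", "NW", "UJ")) {
  name <- match.arg(name)
  n_in <- c(EB = 70, HF = 90, NW = 90, UJ = 70)[[name]]
  schedule <- if (name %in% c("EB", "UJ")) schedule_daily_then_alternate()
              else schedule_weekly_taper()
  chamber <- if (name %in% c("EB", "UJ"))
    chamber_geometry(diameter = 0.38, height = 0.22)
  else
    chamber_geometry(volume = 0.5 * 0.5 * 0.175, area = 0.25)
  omegas <- c(AN = 0.006, Ur = 0.003, UI = 0.0026)
  truths <- lapply(omegas, function(om)
    truth_spec(delta = log(3), k = 0.6, omega = om, sigma_log = 0.8,
               n_in = n_in))
  list(site = name, truths = truths, schedule = schedule,
       layout = campaign_layout(treatments = names(omegas)),
       chamber = chamber, n_in = n_in)
}
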