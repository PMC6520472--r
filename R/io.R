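# Validate a flux observation table. With require_labels = FALSE only the
# numeric columns (day, flux_nmol_m2_s) are mandatory.
validate_flux_obs <- function(x, require_labels = TRUE) {
  if (!is.data.frame(x)) stop("flux observations must be a data.frame")
  need <- c("day", "flux_nmol_m2_s")
  if (require_labels) need <- c("site", "event", "treatment", "plot", need)
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("flux table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(x) == 0L) return(x)
  if (!is.numeric(x$day) || anyNA(x$day))
    stop("column 'day' must be numeric with no missing values")
  if (any(x$day < 0)) stop("column 'day' has negative values")
  if (!is.numeric(x$flux_nmol_m2_s) || anyNA(x$flux_nmol_m2_s) ||
      any(!is.finite(x$flux_nmol_m2_s)))
    stop("column 'flux_nmol_m2_s' must be finite numeric with no missing values")
  x
}

#' Read and write long-format flux observation tables
#'
#' The on-disk format is plain CSV with header
#' `site,event,treatment,plot,day,flux_nmol_m2_s` — one plot-level flux per
#' row, `day` in decimal days since fertiliser application (application
#' instant = day 0). Reading validates types and reports missing columns by
#' name; write/read round-trips are exact to CSV precision (15 significant
#' digits).
#'
#' @param path file path
#' @return data.frame of flux observations
#' @export
read_flux_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_flux_obs(x, require_labels = TRUE)
}

#' @rdname read_flux_table
#' @param observations data.frame to write
#' @export
write_flux_table <- function(observations, path) {
  obs <- validate_flux_obs(observations, require_labels = TRUE)
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event metadata table
#'
#' CSV with header `site,event,date,n_in_kg_ha`: one row per fertilisation
#' event giving the applied N (kg N ha^-1) and application date.
#'
#' @param path file path
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "event", "n_in_kg_ha")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("event table is missing column(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(x$n_in_kg_ha) || any(x$n_in_kg_ha <= 0))
    stop("column 'n_in_kg_ha' must be numeric and > 0")
  x
}

#' Read chamber concentration series
#'
#' CSV with header `chamber_id,time_s,n2o_nmol_mol`: raw headspace samples,
#' several rows per chamber closure.
#'
#' @param path file path
#' @export
read_concentration_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chamber_id", "time_s", "n2o_nmol_mol")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("concentration table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (!is.numeric(x$time_s) || !is.numeric(x$n2o_nmol_mol))
    stop("time_s and n2o_nmol_mol must be numeric")
  x
}

#' Serialize posterior chains to CSV plus a JSON metadata sidecar
#'
#' One row per draw (chain, iter, parameters, derived cumulative and EF);
#' the sidecar records the run configuration, priors and diagnostics needed
#' to interpret the draws.
#'
#' @param chains a `posterior_chains` object
#' @param path CSV path; metadata goes to `<path>.meta.json`
#' @export
write_chains <- function(chains, path) {
  stopifnot(inherits(chains, "posterior_chains"))
  utils::write.csv(as.data.frame(chains), path, row.names = FALSE,
                   quote = FALSE)
  meta <- list(
    n_chains = length(chains$chains),
    n_draws_per_chain = nrow(chains$chains[[1L]]),
    n_obs = chains$n_obs,
    n_in_kg_ha = chains$n_in,
    window_days = chains$window_days,
    background_rate_kg_ha_day = chains$background_rate,
    background_cumulative_kg_ha = chains$background_cumulative,
    acceptance = as.data.frame(chains$acceptance),
    rhat = as.list(chains$rhat),
    priors = unclass(chains$priors),
    config = unclass(chains$config))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Truth sidecar for synthetic campaigns
#'
#' Writes/reads the generator's ground truth as JSON so that recovery tests
#' can compare estimates against what was simulated.
#'
#' @param truths named list of [truth_spec()] objects (one per treatment)
#' @param path JSON path
#' @export
write_truth_sidecar <- function(truths, path) {
  stopifnot(all(vapply(truths, inherits, logical(1), "truth_spec")))
  jsonlite::write_json(lapply(truths, unclass), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_sidecar
#' @export
read_truth_sidecar <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x) do.call(truth_spec, as.list(x)))
}

#' Per-event emission factors from a UK grassland fertiliser trial
#'
#' A packaged example of the EventResult table shape: 30-day cumulative N2O
#' fluxes and emission factors for 11 fertilisation events at four UK
#' grassland sites (EB, HF, NW, UJ), each with ammonium nitrate (AN), urea
#' (Ur) and inhibitor-treated urea (UI) treatments — 33 rows. Columns give
#' the control-plot background, the trapezoidal ("linear") and Bayesian
#' cumulative fluxes with the 95% credible interval, the background-corrected
#' versions, and both EFs (%). Values are as printed in the trial's report
#' tables (2 decimal places), so consistency checks need a rounding tolerance
#' of ~0.015.
#'
#' @return data.frame with 33 rows
#' @export
uk_grassland_efs <- function() {
  path <- system.file("extdata", "uk_grassland_efs.csv", package = "n2oflux")
  if (path == "") stop("packaged dataset not found")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$treatment <- factor(x$treatment, levels = c("AN", "Ur", "UI"))
  x
}
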