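#' Unit conversion between chamber flux and field cumulative-flux scales
#'
#' Chamber fluxes are measured in nmol N2O m^-2 s^-1; cumulative emissions and
#' fertiliser inputs are reported in kg N ha^-1. One nmol of N2O carries two
#' atoms of N (molar mass 14.0067 g mol^-1), so
#' 1 nmol N2O m^-2 s^-1 = 2 x 14.0067 g mol^-1 x 1e-9 x 86400 s day^-1
#' x 1e4 m^2 ha^-1 x 1e-3 kg g^-1 = 0.0242036 kg N ha^-1 day^-1.
#'
#' @param flux numeric, flux in nmol N2O m^-2 s^-1 (vectorised)
#' @return emission rate in kg N ha^-1 day^-1
#' @export
#' @examples
#' convert_flux_units(1)      # 0.0242036
#' convert_flux_units(0.4) * 30  # ~0.29 kg N/ha over a 30-day window
convert_flux_units <- function(flux) {
  stopifnot(is.numeric(flux))
  if (any(!is.finite(flux))) stop("flux must be finite")
  flux * flux_unit_factor()
}

#' @rdname convert_flux_units
#' @param rate numeric, emission rate in kg N ha^-1 day^-1
#' @export
convert_rate_to_flux <- function(rate) {
  stopifnot(is.numeric(rate))
  rate / flux_unit_factor()
}

#' @rdname convert_flux_units
#' @export
flux_unit_factor <- function() {
  molar_mass_n <- 14.0067       # g mol^-1
  2 * molar_mass_n * 1e-9 * 86400 * 1e4 * 1e-3
}
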