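#' Rate law of the spontaneous formaldehyde-THF condensation
#'
#' The in vitro rate of 5,10-methylene-THF formation is
#' k_forward * [HCHO] * [THF] * [H+], with k_forward = 8.7e8 s^-1 M^-2.
#' Rates are carried internally in SI units (M, s) and converted to the
#' biomass-specific unit mmol gCDW^-1 h^-1 at the interface using the
#' intracellular biomass density. The extracellular formaldehyde
#' concentration is used as a proxy for the intracellular one (the
#' intracellular level may be somewhat higher); the reverse reaction
#' (5,10-methylene-THF dissociation) is not modelled, so in vivo values
#' derived elsewhere in the package are net rates.
#'
#' @name condensation
NULL

#' Cellular conversion constants
#'
#' @param biomass_per_od Culture biomass per OD600, mgCDW mL^-1 OD600^-1
#'   (default 0.39).
#' @param intracellular_density Intracellular biomass density, mgCDW mL^-1
#'   (default 300).
#' @param ph Cytosolic pH (default 7.5); the proton concentration is
#'   computed as 10^-pH M.
#' @param carbon_fraction_c1 Fraction of biomass carbon derived from
#'   non-thymidine C1 moieties (default 0.023).
#' @param k_forward Forward rate constant of the condensation,
#'   s^-1 M^-2 (default 8.7e8).
#' @param free_thf_fraction Fraction of the THF/5,10-methylene-THF pool
#'   assumed to be free THF (default 1, the most permissive assumption).
#' @return A `cell_constants` list; `h_conc` holds [H+] in M.
#' @export
cell_constants <- function(biomass_per_od = 0.39,
                           intracellular_density = 300,
                           ph = 7.5,
                           carbon_fraction_c1 = 0.023,
                           k_forward = 8.7e8,
                           free_thf_fraction = 1) {
  stopifnot(biomass_per_od > 0, intracellular_density > 0, ph > 0,
            carbon_fraction_c1 > 0, carbon_fraction_c1 <= 1, k_forward > 0,
            free_thf_fraction > 0, free_thf_fraction <= 1)
  structure(list(biomass_per_od = biomass_per_od,
                 intracellular_density = intracellular_density,
                 ph = ph, h_conc = 10^(-ph),
                 carbon_fraction_c1 = carbon_fraction_c1,
                 k_forward = k_forward,
                 free_thf_fraction = free_thf_fraction),
            class = "cell_constants")
}

#' Read/write cell constants as JSON config
#' @param consts A [cell_constants()] object.
#' @param path File path.
#' @return `write_cell_constants` returns `path` invisibly;
#'   `read_cell_constants` returns a [cell_constants()].
#' @export
write_cell_constants <- function(consts, path) {
  jsonlite::write_json(unclass(consts)[setdiff(names(consts), "h_conc")],
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cell_constants
#' @export
read_cell_constants <- function(path) {
  do.call(cell_constants, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Convert a culture-normalized metabolite pool to intracellular concentration
#'
#' A pool measured per culture volume per OD600 (pmol mL^-1 OD600^-1) is
#' converted to an intracellular concentration by dividing by the biomass
#' per OD and multiplying by the intracellular biomass density:
#' e.g. the measured THF pool of 23 pmol mL^-1 OD600^-1 corresponds to
#' about 18 uM.
#'
#' @param pool Pool size, pmol mL^-1 OD600^-1 (>= 0).
#' @param consts [cell_constants()].
#' @return Intracellular concentration, uM.
#' @export
pool_to_intracellular <- function(pool, consts = cell_constants()) {
  if (any(pool < 0)) stop("pool must be non-negative", call. = FALSE)
  # pmol/mL/OD / (mgCDW/mL/OD) = pmol/mgCDW; x mgCDW/mL = pmol/mL = nM; /1000 = uM
  pool / consts$biomass_per_od * consts$intracellular_density / 1000
}

#' Evaluate the in vitro condensation rate law
#'
#' @param formaldehyde_M,thf_M,h_M Concentrations in M; `h_M` defaults to
#'   the constants' proton concentration.
#' @param consts [cell_constants()].
#' @return List with `volumetric_M_s` (M s^-1) and `biomass_mmol_gcdw_h`
#'   (mmol gCDW^-1 h^-1).
#' @export
in_vitro_rate <- function(formaldehyde_M, thf_M, h_M = consts$h_conc,
                          consts = cell_constants()) {
  stopifnot(formaldehyde_M >= 0, thf_M >= 0, h_M >= 0)
  vol <- consts$k_forward * formaldehyde_M *
    (thf_M * consts$free_thf_fraction) * h_M
  list(volumetric_M_s = vol,
       biomass_mmol_gcdw_h = volumetric_to_biomass(vol, consts))
}

#' Convert between volumetric and biomass-specific rates
#'
#' @param rate_M_s Volumetric rate, M s^-1.
#' @param rate_mmol_gcdw_h Biomass-specific rate, mmol gCDW^-1 h^-1.
#' @param consts [cell_constants()].
#' @return The converted rate.
#' @export
volumetric_to_biomass <- function(rate_M_s, consts = cell_constants()) {
  # M/s -> mol/L/h -> mol/gCDW/h (density mg/mL = g/L) -> mmol/gCDW/h
  rate_M_s * 3600 / consts$intracellular_density * 1000
}

#' @rdname volumetric_to_biomass
#' @export
biomass_to_volumetric <- function(rate_mmol_gcdw_h, consts = cell_constants()) {
  rate_mmol_gcdw_h / 3600 * consts$intracellular_density / 1000
}

#' Fold difference between in vivo and in vitro rates
#'
#' @param in_vivo,in_vitro Rates in the same unit (mmol gCDW^-1 h^-1);
#'   `in_vitro` must be positive.
#' @return in_vivo / in_vitro.
#' @export
fold_difference <- function(in_vivo, in_vitro) {
  if (any(in_vitro <= 0)) stop("in vitro rate must be positive", call. = FALSE)
  in_vivo / in_vitro
}

#' Direct biomass-fraction growth estimate
#'
#' If a measured growth rate is sustained with the condensation supplying
#' only the non-thymidine C1 moieties (a fraction `carbon_fraction` of
#' biomass carbon), the growth rate expected when the condensation supplies
#' all biomass carbon is their product: e.g. 0.036 h^-1 x 0.023 = 0.0008 h^-1.
#'
#' @param mu_measured Measured growth rate, h^-1 (> 0).
#' @param carbon_fraction Fraction of biomass carbon from non-thymidine C1
#'   moieties, in (0, 1].
#' @return Estimated growth rate, h^-1.
#' @export
direct_growth_estimate <- function(mu_measured,
                                   carbon_fraction =
                                     cell_constants()$carbon_fraction_c1) {
  stopifnot(mu_measured > 0, carbon_fraction > 0, carbon_fraction <= 1)
  mu_measured * carbon_fraction
}
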