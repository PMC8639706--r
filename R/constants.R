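#' Reference constants for nitrogen isotope and oxygen stoichiometry
#'
#' `R15_AIR` is the isotope ratio (15N/14N) of atmospheric N2, the reference
#' for delta-15N. `O2_PER_NO2_OXIDATION` is the moles of O2 consumed per mole
#' of nitrite oxidized to nitrate (half a mole: one O atom appended to the N
#' oxide). `O2_PER_NH4_OXIDATION` is the canonical oxygen demand of ammonia
#' oxidation to nitrite (1.5 mol O2 per mol N).
#'
#' @name nitroxr-constants
#' @keywords datasets
NULL

#' @rdname nitroxr-constants
#' @export
R15_AIR <- 0.0036765

#' @rdname nitroxr-constants
#' @export
O2_PER_NO2_OXIDATION <- 0.5

#' @rdname nitroxr-constants
#' @export
O2_PER_NH4_OXIDATION <- 1.5

#' Natural abundance of 15N
#'
#' Atom percent (or atom fraction) of 15N at natural abundance, computed from
#' the air N2 reference ratio: 100 * R / (1 + R) with R = `R15_AIR`, i.e.
#' 0.3663 at%.
#'
#' @return `nat_abundance_atpct()`: atom percent (0-100).
#'   `nat_abundance_frac()`: atom fraction (0-1).
#' @export
#' @examples
#' nat_abundance_atpct()
nat_abundance_atpct <- function() 100 * R15_AIR / (1 + R15_AIR)

#' @rdname nat_abundance_atpct
#' @export
nat_abundance_frac <- function() R15_AIR / (1 + R15_AIR)

#' Convert delta-15N measurement precision to atom-percent precision
#'
#' Linearizes the delta -> atom percent conversion at natural abundance, so a
#' per-mil measurement precision (0.3 permil for delta-15N on a typical
#' denitrifier-method run) can be used as the atom-percent noise level of
#' tracer endpoint measurements.
#'
#' @param sd_permil standard deviation of the delta-15N measurement, permil.
#' @return standard deviation in atom percent.
#' @export
atpct_sd_from_permil <- function(sd_permil = 0.3) {
  # d(at%)/d(delta) = 100 * (R15/1000) / (1 + R)^2 evaluated at delta = 0
  100 * (R15_AIR / 1000) / (1 + R15_AIR)^2 * sd_permil
}
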