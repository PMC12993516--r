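#' Microcosm configuration
#'
#' All experiment constants consumed by the mixing-model inversion and the
#' rate normalizations, with defaults matching a 120 mL serum-bottle
#' incubation: 100 mL aqueous phase, one ~0.33 g drop of light oil, a
#' 10 atom% 13C bicarbonate buffer measured at 7.58 mM total CO2, substrate
#' carbon at 1.075 atom% 13C, and a 16.61 cm2 oil-water contact (OWC) area.
#' The electron bookkeeping assumes average oil carbon at oxidation state
#' -II (a CH2 unit, 14.0266 g/mol), i.e. 6 electrons released per carbon
#' fully oxidised to CO2, and 8 electrons consumed per sulfate reduced to
#' sulfide.
#'
#' @param aqueous_volume_L Aqueous-phase volume, litres.
#' @param oil_mass_g Mass of the oil drop, grams.
#' @param buffer_total_co2_mM Total CO2 (DIC) in the labelled buffer, mM.
#' @param buffer_atom_pct 13C atom percent of the buffer.
#' @param substrate_atom_pct 13C atom percent of the substrate oil.
#' @param owc_area_m2 Oil-water contact area, square metres.
#' @param ch2_molar_mass Molar mass of a CH2 unit, g/mol.
#' @param electrons_per_carbon Electrons released per substrate carbon
#'   oxidised to CO2.
#' @param electrons_per_sulfate Electrons consumed per sulfate reduced to
#'   hydrogen sulfide.
#' @return An object of class `microcosm_config`.
#' @examples
#' microcosm_config()
#' microcosm_config(oil_mass_g = 0.42)
#' @export
microcosm_config <- function(aqueous_volume_L = 0.100,
                             oil_mass_g = 0.33,
                             buffer_total_co2_mM = 7.58,
                             buffer_atom_pct = 10.0,
                             substrate_atom_pct = 1.075,
                             owc_area_m2 = 16.61e-4,
                             ch2_molar_mass = 14.0266,
                             electrons_per_carbon = 6,
                             electrons_per_sulfate = 8) {
  cfg <- list(aqueous_volume_L = aqueous_volume_L,
              oil_mass_g = oil_mass_g,
              buffer_total_co2_mM = buffer_total_co2_mM,
              buffer_atom_pct = buffer_atom_pct,
              substrate_atom_pct = substrate_atom_pct,
              owc_area_m2 = owc_area_m2,
              ch2_molar_mass = ch2_molar_mass,
              electrons_per_carbon = electrons_per_carbon,
              electrons_per_sulfate = electrons_per_sulfate)
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(errorCondition(sprintf("config field '%s' must be a single positive number", nm),
                          class = c("rsil_invalid_config", "rsil_error")))
    }
  }
  if (cfg$buffer_atom_pct <= cfg$substrate_atom_pct) {
    stop(errorCondition(
      "buffer atom percent must exceed the substrate atom percent",
      class = c("rsil_invalid_config", "rsil_error")))
  }
  structure(cfg, class = "microcosm_config")
}

#' @export
print.microcosm_config <- function(x, ...) {
  cat("Microcosm configuration:\n")
  for (nm in names(unclass(x))) {
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

#' Buffer carbon pool implied by a configuration
#'
#' @param config A [microcosm_config()].
#' @return A [carbon_pool()] for the labelled buffer.
#' @export
buffer_pool <- function(config) {
  stopifnot(inherits(config, "microcosm_config"))
  carbon_pool(config$buffer_total_co2_mM, config$buffer_atom_pct)
}
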