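#' Transparent headline arithmetic from endpoint summaries
#'
#' Given the endpoint summaries of an incubation — cumulative produced CO2
#' (mM), its duration (days) and the initial/final sulfate concentrations —
#' computes every derived headline number in one transparent, unrounded
#' chain: total CO2 (mmol), overall rate (mmol/yr), the per-gram-oil,
#' per-mol-CH2 and per-OWC-area normalizations, total sulfate reduced and
#' its rate, the electron balance, and the implied oil mass consumed.
#'
#' Published summaries of such experiments are often computed step-by-step
#' from already-rounded intermediates, so recomputing the chain from the
#' printed endpoints can disagree with printed derived values by a few
#' percent. This function is the package's single source of truth for the
#' chain; use it to surface such rounding gaps rather than propagating them.
#'
#' @param cum_co2_mM Cumulative produced CO2 at the end of the incubation, mM.
#' @param total_days Incubation length, days.
#' @param sulfate_initial_mM,sulfate_final_mM Sulfate at start and end, mM.
#' @param config A [microcosm_config()].
#' @return A named list of headline quantities (see Details), each an
#'   unrounded number.
#' @examples
#' transparent_chain(8.31, 857, 20.6, 15.2, microcosm_config())
#' @export
transparent_chain <- function(cum_co2_mM, total_days,
                              sulfate_initial_mM = NA_real_,
                              sulfate_final_mM = NA_real_,
                              config = microcosm_config()) {
  stopifnot(inherits(config, "microcosm_config"),
            cum_co2_mM >= 0, total_days > 0)
  total_mmol <- cum_co2_mM * config$aqueous_volume_L
  overall <- rate_estimate(total_mmol / total_days * 365, "mmol/yr",
                           c(0, total_days))
  per_g <- normalize_rate(overall, config, "per_g_oil")
  per_ch2 <- normalize_rate(overall, config, "per_mol_ch2")
  per_owc <- normalize_rate(overall, config, "per_owc_area")
  out <- list(
    cum_co2_mM = cum_co2_mM,
    total_co2_mmol = total_mmol,
    overall_rate_mmol_yr = overall$value,
    rate_per_g_oil_mmol_g_yr = per_g$value,
    rate_per_mol_ch2_mmol_mol_yr = per_ch2$value,
    rate_per_owc_g_m2_yr = per_owc$value,
    oil_consumed_mg = oil_consumed_mass(total_mmol, config))
  if (is.finite(sulfate_initial_mM) && is.finite(sulfate_final_mM)) {
    s <- sulfate_reduced(
      data.frame(day = c(0, total_days),
                 sulfate_mM = c(sulfate_initial_mM, sulfate_final_mM)),
      config)
    eb <- electron_balance(cum_co2_mM,
                           sulfate_initial_mM - sulfate_final_mM, config)
    out$sulfate_reduced_mmol <- s$total_mmol
    out$sulfate_rate_mmol_yr <- s$rate$value
    out$fraction_to_sulfate <- eb$fraction_to_sulfate
    out$fraction_to_biomass <- eb$fraction_to_biomass
  }
  out
}
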