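rate_units <- c("mM/yr", "mmol/yr", "mmol/g/yr", "mmol/molCH2/yr",
                "gCH2/m2/yr", "mmolSO4/yr")

#' Rate estimate
#'
#' A rate with its units, the day interval it was estimated over, the
#' estimation method and the replicate it belongs to. Constructed by
#' [estimate_rate()] and transformed by [to_amount_rate()] and
#' [normalize_rate()]; rarely built by hand.
#'
#' @param value Numeric rate value.
#' @param units One of `"mM/yr"`, `"mmol/yr"`, `"mmol/g/yr"`,
#'   `"mmol/molCH2/yr"`, `"gCH2/m2/yr"`, `"mmolSO4/yr"`.
#' @param interval Length-2 numeric, `[day_start, day_end]` with start < end.
#' @param method `"endpoint"` or `"ols"`.
#' @param replicate_id Microcosm identifier or `"pooled"`.
#' @param sd Standard deviation across replicates (NA for a single series).
#' @param n Number of replicates averaged.
#' @return An object of class `rate_estimate`.
#' @export
rate_estimate <- function(value, units, interval, method = "endpoint",
                          replicate_id = "pooled", sd = NA_real_, n = 1L) {
  if (!units %in% rate_units) {
    stop(errorCondition(sprintf("unknown rate units '%s'", units),
                        class = c("rsil_unit_mismatch", "rsil_error")))
  }
  if (length(interval) != 2L || !is.numeric(interval) ||
      interval[1] >= interval[2]) {
    stop(errorCondition("interval must be [day_start, day_end] with start < end",
                        class = c("rsil_invalid_interval", "rsil_error")))
  }
  structure(list(value = value, units = units,
                 interval = as.numeric(interval), method = method,
                 replicate_id = replicate_id, sd = sd, n = as.integer(n)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s rate [%s]: %.4g %s (days %g-%g%s)\n",
              x$replicate_id, x$method, x$value, x$units,
              x$interval[1], x$interval[2],
              if (is.finite(x$sd)) sprintf(", sd %.3g, n=%d", x$sd, x$n) else ""))
  invisible(x)
}

#' Estimate a production rate from a time series
#'
#' Two estimators over a chosen day interval: `endpoint` is the difference
#' between the last and first points divided by the elapsed days (the
#' convention used for the headline cumulative rates), and `ols` is the
#' least-squares slope of value vs day. Both are converted to a per-year
#' rate with a 365-day year; on a noiseless linear series they coincide.
#'
#' @param series A data frame with columns `day` and `produced_mM` (or
#'   another concentration column named by `value_col`).
#' @param interval Length-2 numeric day range; defaults to the full series.
#' @param method `"endpoint"` or `"ols"`.
#' @param replicate_id Identifier carried into the result.
#' @param value_col Name of the concentration column.
#' @param units Units of the resulting rate (concentration per year).
#' @return A [rate_estimate()] in `units`.
#' @examples
#' s <- data.frame(day = c(0, 857), produced_mM = c(0, 8.31))
#' estimate_rate(s)  # 3.54 mM/yr
#' @export
estimate_rate <- function(series, interval = NULL,
                          method = c("endpoint", "ols"),
                          replicate_id = "pooled",
                          value_col = "produced_mM",
                          units = "mM/yr") {
  method <- match.arg(method)
  stopifnot(is.data.frame(series), value_col %in% names(series),
            "day" %in% names(series))
  if (is.null(interval)) interval <- range(series$day)
  s <- series[series$day >= interval[1] & series$day <= interval[2] &
                !is.na(series[[value_col]]), , drop = FALSE]
  s <- s[order(s$day), , drop = FALSE]
  if (nrow(s) < 2L) {
    stop(errorCondition(
      sprintf("need at least 2 points in [%g, %g] to estimate a rate (%s)",
              interval[1], interval[2], replicate_id),
      class = c("rsil_insufficient_data", "rsil_error")))
  }
  v <- s[[value_col]]
  slope_per_day <- switch(method,
    endpoint = (v[nrow(s)] - v[1]) / (s$day[nrow(s)] - s$day[1]),
    ols = unname(stats::coef(stats::lm(v ~ s$day))[2]))
  rate_estimate(slope_per_day * 365, units = units, interval = interval,
                method = method, replicate_id = replicate_id)
}

#' Average rate across replicates
#'
#' Arithmetic mean of replicate [rate_estimate()]s sharing units, method and
#' interval; the across-replicate standard deviation is reported alongside.
#'
#' @param rates A list of [rate_estimate()] objects.
#' @return A pooled [rate_estimate()] with `sd` and `n` filled in.
#' @examples
#' iv <- c(0, 122)
#' rs <- lapply(c(18.17, 15.27, 19.29, 17.61), rate_estimate,
#'              units = "mM/yr", interval = iv)
#' mean_replicate_rate(rs)  # 17.585 mM/yr
#' @export
mean_replicate_rate <- function(rates) {
  stopifnot(length(rates) >= 1L,
            all(vapply(rates, inherits, logical(1), "rate_estimate")))
  units <- unique(vapply(rates, `[[`, character(1), "units"))
  ivals <- unique(vapply(rates, function(r) paste(r$interval, collapse = "-"),
                         character(1)))
  if (length(units) != 1L) {
    stop(errorCondition("cannot average rates with mixed units",
                        class = c("rsil_unit_mismatch", "rsil_error")))
  }
  if (length(ivals) != 1L) {
    stop(errorCondition("cannot average rates over different intervals",
                        class = c("rsil_invalid_interval", "rsil_error")))
  }
  vals <- vapply(rates, `[[`, numeric(1), "value")
  rate_estimate(mean(vals), units = units, interval = rates[[1]]$interval,
                method = rates[[1]]$method, replicate_id = "pooled",
                sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
                n = length(vals))
}

#' Concentration rate to amount rate
#'
#' Multiplies a mM/yr rate by the aqueous volume to give mmol/yr per
#' microcosm.
#'
#' @param rate A [rate_estimate()] in mM/yr (or mmolSO4-equivalent mM/yr).
#' @param config A [microcosm_config()].
#' @return A [rate_estimate()] in mmol/yr.
#' @export
to_amount_rate <- function(rate, config) {
  stopifnot(inherits(rate, "rate_estimate"), inherits(config, "microcosm_config"))
  if (rate$units != "mM/yr") {
    stop(errorCondition("to_amount_rate expects a rate in mM/yr",
                        class = c("rsil_unit_mismatch", "rsil_error")))
  }
  out <- rate
  out$value <- rate$value * config$aqueous_volume_L
  out$sd <- rate$sd * config$aqueous_volume_L
  out$units <- "mmol/yr"
  out
}

#' Normalize a per-microcosm rate
#'
#' Expresses a per-microcosm mmol/yr rate on one of three comparison bases:
#' * `per_g_oil` — divide by the oil mass (mmol per g oil per year);
#' * `per_mol_ch2` — divide by the moles of CH2 units in the oil drop,
#'   oil_mass / M(CH2) (mmol per mol CH2 per year);
#' * `per_owc_area` — convert mmol CO2 to grams of CH2 consumed (1 mol CO2
#'   per mol CH2) and divide by the oil-water contact area
#'   (g CH2 per m2 OWC per year).
#'
#' @param rate A [rate_estimate()] in mmol/yr.
#' @param config A [microcosm_config()].
#' @param basis `"per_g_oil"`, `"per_mol_ch2"` or `"per_owc_area"`.
#' @return A [rate_estimate()] in the corresponding units.
#' @examples
#' r <- rate_estimate(0.35, "mmol/yr", c(0, 857))
#' normalize_rate(r, microcosm_config(), "per_g_oil")  # 1.06 mmol/g/yr
#' @export
normalize_rate <- function(rate, config,
                           basis = c("per_g_oil", "per_mol_ch2", "per_owc_area")) {
  stopifnot(inherits(rate, "rate_estimate"), inherits(config, "microcosm_config"))
  basis <- match.arg(basis)
  if (rate$units != "mmol/yr") {
    stop(errorCondition("normalize_rate expects a rate in mmol/yr",
                        class = c("rsil_unit_mismatch", "rsil_error")))
  }
  out <- rate
  scale <- switch(basis,
    per_g_oil = 1 / config$oil_mass_g,
    per_mol_ch2 = 1 / (config$oil_mass_g / config$ch2_molar_mass),
    # mmol * (mg/mmol) / 1000 -> g, then / m2
    per_owc_area = config$ch2_molar_mass / 1000 / config$owc_area_m2)
  out$value <- rate$value * scale
  out$sd <- rate$sd * scale
  out$units <- switch(basis,
    per_g_oil = "mmol/g/yr",
    per_mol_ch2 = "mmol/molCH2/yr",
    per_owc_area = "gCH2/m2/yr")
  out
}

#' Sulfate reduced over an incubation
#'
#' Endpoint accounting of electron-acceptor consumption: the concentration
#' drop between the first and last time points times the aqueous volume
#' gives the total mmol of sulfate reduced; dividing by the elapsed time
#' gives a mean reduction rate in mmol/yr. An apparent sulfate increase is
#' flagged, not treated as an error.
#'
#' @param series A data frame with columns `day` and `sulfate_mM`.
#' @param config A [microcosm_config()].
#' @param replicate_id Identifier carried into the rate.
#' @return A list with `total_mmol`, `rate` (a [rate_estimate()] in
#'   mmolSO4/yr) and `flagged_increase`.
#' @examples
#' s <- data.frame(day = c(0, 857), sulfate_mM = c(20.6, 15.2))
#' sulfate_reduced(s, microcosm_config())  # 0.54 mmol, 0.23 mmol/yr
#' @export
sulfate_reduced <- function(series, config, replicate_id = "pooled") {
  stopifnot(is.data.frame(series), inherits(config, "microcosm_config"),
            all(c("day", "sulfate_mM") %in% names(series)))
  s <- series[!is.na(series$sulfate_mM), , drop = FALSE]
  s <- s[order(s$day), , drop = FALSE]
  if (nrow(s) < 2L) {
    stop(errorCondition("need at least 2 sulfate points",
                        class = c("rsil_insufficient_data", "rsil_error")))
  }
  delta_mM <- s$sulfate_mM[1] - s$sulfate_mM[nrow(s)]
  total_mmol <- delta_mM * config$aqueous_volume_L
  span <- s$day[nrow(s)] - s$day[1]
  rate <- rate_estimate(total_mmol / span * 365, units = "mmolSO4/yr",
                        interval = c(s$day[1], s$day[nrow(s)]),
                        method = "endpoint", replicate_id = replicate_id)
  list(total_mmol = total_mmol, rate = rate,
       flagged_increase = delta_mM < 0)
}

#' Electron balance between CO2 evolution and sulfate reduction
#'
#' Oxidising one CH2-unit carbon (oxidation state -II) to CO2 (+IV) releases
#' 6 electrons; reducing one sulfate to hydrogen sulfide consumes 8. The
#' balance compares donor electrons (evolved CO2 times 6) with acceptor
#' electrons (sulfate reduced times 8); any shortfall on the acceptor side
#' is attributed to biomass synthesis, the usual assimilatory sink for
#' sulfate-reducing communities.
#'
#' @param co2_evolved_mM Cumulative substrate-derived CO2, mM (>= 0).
#' @param sulfate_reduced_mM Sulfate consumed, mM (>= 0).
#' @param config A [microcosm_config()].
#' @return An object of class `electron_balance` with fields
#'   `donor_electrons_me_L`, `acceptor_electrons_me_L`, `fraction_to_sulfate`,
#'   `fraction_to_biomass` and `flagged_inconsistent` (acceptor exceeding
#'   donor, or acceptor without donor).
#' @examples
#' electron_balance(8.3, 5.4, microcosm_config())  # ~87% to sulfate
#' @export
electron_balance <- function(co2_evolved_mM, sulfate_reduced_mM, config) {
  stopifnot(inherits(config, "microcosm_config"))
  if (co2_evolved_mM < 0 || sulfate_reduced_mM < 0) {
    stop(errorCondition("electron balance inputs must be non-negative",
                        class = c("rsil_domain_error", "rsil_error")))
  }
  donor <- co2_evolved_mM * config$electrons_per_carbon
  acceptor <- sulfate_reduced_mM * config$electrons_per_sulfate
  if (donor == 0) {
    frac_s <- if (acceptor == 0) 0 else NA_real_
  } else {
    frac_s <- acceptor / donor
  }
  structure(list(
    donor_electrons_me_L = donor,
    acceptor_electrons_me_L = acceptor,
    fraction_to_sulfate = frac_s,
    fraction_to_biomass = if (is.na(frac_s)) NA_real_ else 1 - frac_s,
    flagged_inconsistent = is.na(frac_s) || frac_s > 1
  ), class = "electron_balance")
}

#' @export
print.electron_balance <- function(x, ...) {
  cat(sprintf(paste0(
    "Electron balance: donor %.4g me-/L, acceptor %.4g me-/L\n",
    "  to sulfate: %.1f%%   to biomass: %.1f%%%s\n"),
    x$donor_electrons_me_L, x$acceptor_electrons_me_L,
    100 * x$fraction_to_sulfate, 100 * x$fraction_to_biomass,
    if (isTRUE(x$flagged_inconsistent)) "   [FLAG: inconsistent]" else ""))
  invisible(x)
}

#' Oil mass consumed implied by cumulative CO2
#'
#' Under the 1 mol CO2 per mol CH2 assumption, each mmol of evolved CO2
#' corresponds to M(CH2) milligrams of oil consumed.
#'
#' @param co2_total_mmol Cumulative CO2 evolved, mmol (>= 0).
#' @param config A [microcosm_config()].
#' @return Oil consumed, mg.
#' @export
oil_consumed_mass <- function(co2_total_mmol, config) {
  stopifnot(inherits(config, "microcosm_config"))
  if (any(co2_total_mmol < 0)) {
    stop(errorCondition("cumulative CO2 must be non-negative",
                        class = c("rsil_domain_error", "rsil_error")))
  }
  co2_total_mmol * config$ch2_molar_mass
}
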