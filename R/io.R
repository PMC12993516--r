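measurement_columns <- c("day", "microcosm_id", "treatment",
                         "delta13c_permil", "sulfate_mM", "cells_per_ml")

#' Read a microcosm measurement table
#'
#' Reads the long-format CSV exchange schema: one row per (day, microcosm)
#' with columns `day`, `microcosm_id`, `treatment` (live/autoclaved) and the
#' nullable measurement columns `delta13c_permil`, `sulfate_mM`,
#' `cells_per_ml`. Every row must carry at least one measurement, and a
#' (day, microcosm) pair may report each variable at most once.
#'
#' @param path Path to a CSV file (RFC-4180, UTF-8, '.' decimal).
#' @param strict If `TRUE`, columns outside the documented schema are an
#'   error; otherwise they are dropped with a warning.
#' @return A validated data frame in schema column order.
#' @export
read_measurements <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("measurement file not found: %s", path),
                        class = c("rsil_parse_error", "rsil_error")))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) {
      stop(errorCondition(sprintf("cannot parse %s: %s", path,
                                  conditionMessage(e)),
                          class = c("rsil_parse_error", "rsil_error")))
    })
  validate_measurements(df, strict = strict, source = path)
}

#' Validate an in-memory measurement table
#'
#' @param df A data frame candidate for the measurement schema.
#' @inheritParams read_measurements
#' @param source Label used in error messages.
#' @return The validated data frame.
#' @export
validate_measurements <- function(df, strict = FALSE, source = "measurements") {
  required <- c("day", "microcosm_id", "treatment")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(errorCondition(
      sprintf("%s: missing required columns: %s", source,
              paste(missing_cols, collapse = ", ")),
      class = c("rsil_parse_error", "rsil_error")))
  }
  extra <- setdiff(names(df), measurement_columns)
  if (length(extra) > 0L) {
    if (strict) {
      stop(errorCondition(
        sprintf("%s: unknown columns in strict mode: %s", source,
                paste(extra, collapse = ", ")),
        class = c("rsil_parse_error", "rsil_error")))
    }
    warning(sprintf("%s: ignoring unknown columns: %s", source,
                    paste(extra, collapse = ", ")))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  for (col in setdiff(measurement_columns, names(df))) df[[col]] <- NA_real_
  df <- df[, measurement_columns]

  num_cols <- c("day", "delta13c_permil", "sulfate_mM", "cells_per_ml")
  for (col in num_cols) {
    v <- df[[col]]
    if (is.character(v)) {
      bad <- which(!is.na(v) & v != "" & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad) > 0L) {
        stop(errorCondition(
          sprintf("%s: non-numeric value in column '%s' at data row %d ('%s')",
                  source, col, bad[1], v[bad[1]]),
          class = c("rsil_parse_error", "rsil_error")))
      }
      v[v == ""] <- NA
      df[[col]] <- as.numeric(v)
    }
  }
  if (any(is.na(df$day)) || any(df$day < 0)) {
    stop(errorCondition(sprintf("%s: day must be a non-negative number", source),
                        class = c("rsil_parse_error", "rsil_error")))
  }
  bad_trt <- which(!df$treatment %in% c("live", "autoclaved"))
  if (length(bad_trt) > 0L) {
    stop(errorCondition(
      sprintf("%s: treatment must be 'live' or 'autoclaved' (data row %d)",
              source, bad_trt[1]),
      class = c("rsil_parse_error", "rsil_error")))
  }
  meas_cols <- c("delta13c_permil", "sulfate_mM", "cells_per_ml")
  empty <- which(rowSums(!is.na(df[, meas_cols, drop = FALSE])) == 0L)
  if (length(empty) > 0L) {
    stop(errorCondition(
      sprintf("%s: data row %d has no measurement values", source, empty[1]),
      class = c("rsil_parse_error", "rsil_error")))
  }
  for (col in meas_cols) {
    have <- !is.na(df[[col]])
    key <- paste(df$day[have], df$microcosm_id[have])
    dup <- which(duplicated(key))
    if (length(dup) > 0L) {
      stop(errorCondition(
        sprintf("%s: duplicate %s for (day %g, %s) at data row %d", source,
                col, df$day[have][dup[1]], df$microcosm_id[have][dup[1]],
                which(have)[dup[1]]),
        class = c("rsil_parse_error", "rsil_error")))
    }
  }
  df
}

#' Write a measurement table as CSV
#'
#' Deterministic writer for the exchange schema (stable column order, no
#' row names, '.' decimal): identical inputs give byte-identical files.
#'
#' @param measurements Data frame in the measurement schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  df <- measurements[, measurement_columns]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run the end-to-end microcosm analysis
#'
#' Takes a validated measurement table and a configuration, then runs the
#' full chain per microcosm: delta-13C -> atom percent -> mixing-model
#' inversion -> produced-CO2 series, endpoint (and optionally OLS) rates
#' over the full incubation and the early phase, replicate-pooled rates
#' within treatment groups, amount conversion and the three normalizations,
#' sulfate accounting, the electron balance and the implied oil mass
#' consumed. Live and autoclaved-control replicates are analysed
#' identically but never pooled together.
#'
#' @param measurements Data frame in the measurement schema (see
#'   [read_measurements()]).
#' @param config A [microcosm_config()].
#' @param phase_break End of the early phase, days.
#' @param method Rate estimator, `"endpoint"` (default) or `"ols"`.
#' @param baseline `"anchor_zero"` (default) pins day-0 produced CO2 at
#'   exactly 0 — the buffer starts undiluted by definition, so a day-0
#'   reading only carries instrument noise. `"first_point"` subtracts the
#'   first measured value from the whole series instead; `"none"` uses the
#'   inverted values as-is.
#' @return An object of class `rsil_report`: a list with `produced`,
#'   `rates` (tidy data frame), `sulfate`, `electron_balance`,
#'   `oil_consumed_mg`, `flags`, `warnings` and provenance (`config`,
#'   `version`).
#' @examples
#' sim <- simulate_microcosms(simulation_params(seed = 3))
#' rep <- run_analysis(sim$measurements, microcosm_config())
#' rep$rates[rep$rates$microcosm_id == "pooled", ]
#' @export
run_analysis <- function(measurements, config = microcosm_config(),
                         phase_break = 122, method = "endpoint",
                         baseline = c("anchor_zero", "first_point", "none")) {
  baseline <- match.arg(baseline)
  df <- validate_measurements(measurements, strict = FALSE)
  df <- df[order(df$microcosm_id, df$day), ]
  buf <- buffer_pool(config)
  warns <- character(0)

  has_delta <- !is.na(df$delta13c_permil)
  ids <- unique(df$microcosm_id)
  trt_of <- vapply(ids, function(id) df$treatment[df$microcosm_id == id][1],
                   character(1))
  live_ids <- ids[trt_of == "live"]
  ctrl_ids <- ids[trt_of == "autoclaved"]
  if (length(live_ids) == 0L) {
    warns <- c(warns, "no live replicates: rates reported for controls only")
  }

  # per-replicate produced-CO2 series
  produced <- list()
  for (id in ids) {
    m <- df[df$microcosm_id == id & has_delta, ]
    if (nrow(m) == 0L) next
    ps <- produced_series(m[, c("day", "delta13c_permil")], buf,
                          config$substrate_atom_pct)
    if (baseline == "anchor_zero") {
      ps$produced_mM[ps$day == 0] <- 0
      ps$flagged_negative[ps$day == 0] <- FALSE
    } else if (baseline == "first_point") {
      ps$produced_mM <- ps$produced_mM - ps$produced_mM[1]
      ps$flagged_negative <- ps$produced_mM < 0
    }
    ps$microcosm_id <- id
    ps$treatment <- trt_of[[id]]
    produced[[id]] <- ps
  }
  produced_df <- if (length(produced) > 0L) do.call(rbind, produced)
                 else data.frame(day = numeric(0), produced_mM = numeric(0),
                                 flagged_negative = logical(0),
                                 microcosm_id = character(0),
                                 treatment = character(0))
  rownames(produced_df) <- NULL

  full_interval <- range(df$day)
  early_interval <- c(full_interval[1], min(phase_break, full_interval[2]))
  intervals <- list(full = full_interval)
  if (early_interval[2] > early_interval[1] &&
      early_interval[2] < full_interval[2]) {
    intervals$early <- early_interval
  }

  rate_rows <- list()
  add_rate <- function(r, treatment, basis) {
    rate_rows[[length(rate_rows) + 1L]] <<- data.frame(
      microcosm_id = r$replicate_id, treatment = treatment,
      interval_start_day = r$interval[1], interval_end_day = r$interval[2],
      method = r$method, basis = basis, value = r$value, units = r$units,
      sd = r$sd, n = r$n)
  }

  group_rates <- function(group_ids, treatment) {
    pooled <- list()
    for (iv_name in names(intervals)) {
      iv <- intervals[[iv_name]]
      per_rep <- list()
      for (id in group_ids) {
        ps <- produced[[id]]
        if (is.null(ps)) next
        r <- tryCatch(
          estimate_rate(ps, interval = iv, method = method, replicate_id = id),
          error = function(e) NULL)
        if (is.null(r)) {
          warns <<- c(warns, sprintf(
            "%s: too few points in days %g-%g for a rate", id, iv[1], iv[2]))
          next
        }
        add_rate(r, treatment, "per_microcosm_mM")
        per_rep[[id]] <- r
      }
      if (length(per_rep) > 0L) {
        pr <- mean_replicate_rate(unname(per_rep))
        add_rate(pr, treatment, "per_microcosm_mM")
        pooled[[iv_name]] <- pr
      }
    }
    pooled
  }

  pooled_live <- group_rates(live_ids, "live")
  pooled_ctrl <- group_rates(ctrl_ids, "autoclaved")

  # amount conversion + normalizations for the pooled live full-interval rate
  if (!is.null(pooled_live$full)) {
    amt <- to_amount_rate(pooled_live$full, config)
    add_rate(amt, "live", "per_microcosm_mmol")
    for (basis in c("per_g_oil", "per_mol_ch2", "per_owc_area")) {
      add_rate(normalize_rate(amt, config, basis), "live", basis)
    }
  }

  rates <- if (length(rate_rows) > 0L) do.call(rbind, rate_rows)
           else data.frame()
  rownames(rates) <- NULL

  # sulfate accounting per replicate + pooled within the live group
  sulfate_rows <- list()
  sulf_total_live <- NA_real_
  for (id in ids) {
    m <- df[df$microcosm_id == id & !is.na(df$sulfate_mM), ]
    if (nrow(m) < 2L) next
    sr <- sulfate_reduced(m[, c("day", "sulfate_mM")], config,
                          replicate_id = id)
    sulfate_rows[[id]] <- data.frame(
      microcosm_id = id, treatment = trt_of[[id]],
      total_mmol = sr$total_mmol, rate_mmol_yr = sr$rate$value,
      interval_start_day = sr$rate$interval[1],
      interval_end_day = sr$rate$interval[2],
      flagged_increase = sr$flagged_increase)
  }
  sulfate_df <- if (length(sulfate_rows) > 0L) do.call(rbind, sulfate_rows)
                else data.frame()
  rownames(sulfate_df) <- NULL
  if (nrow(sulfate_df) > 0L) {
    live_s <- sulfate_df[sulfate_df$treatment == "live", ]
    if (nrow(live_s) > 0L) sulf_total_live <- mean(live_s$total_mmol)
  }

  # electron balance on pooled live endpoint quantities (concentration basis)
  eb <- NULL
  co2_final_mM <- NA_real_
  if (length(live_ids) > 0L && nrow(produced_df) > 0L) {
    finals <- vapply(live_ids, function(id) {
      ps <- produced[[id]]
      if (is.null(ps) || nrow(ps) == 0L) return(NA_real_)
      ps$produced_mM[nrow(ps)] - ps$produced_mM[1]
    }, numeric(1))
    co2_final_mM <- mean(finals, na.rm = TRUE)
    if (is.finite(co2_final_mM) && is.finite(sulf_total_live)) {
      eb <- electron_balance(max(co2_final_mM, 0),
                             max(sulf_total_live / config$aqueous_volume_L, 0),
                             config)
    }
  }

  oil_mg <- if (is.finite(co2_final_mM)) {
    oil_consumed_mass(max(co2_final_mM, 0) * config$aqueous_volume_L, config)
  } else NA_real_

  # flags: negative produced CO2, sulfate increases, active-looking controls
  flag_rows <- list()
  neg <- produced_df[produced_df$flagged_negative, , drop = FALSE]
  for (j in seq_len(nrow(neg))) {
    flag_rows[[length(flag_rows) + 1L]] <- data.frame(
      flag = "negative_produced_co2", microcosm_id = neg$microcosm_id[j],
      day = neg$day[j], value = neg$produced_mM[j])
  }
  if (nrow(sulfate_df) > 0L) {
    inc <- sulfate_df[sulfate_df$flagged_increase, , drop = FALSE]
    for (j in seq_len(nrow(inc))) {
      flag_rows[[length(flag_rows) + 1L]] <- data.frame(
        flag = "sulfate_increase", microcosm_id = inc$microcosm_id[j],
        day = inc$interval_end_day[j], value = -inc$total_mmol[j])
    }
  }
  dl <- detection_limit(buf, config$substrate_atom_pct,
                        sigma_atom_pct = 0.001)
  for (id in ctrl_ids) {
    ps <- produced[[id]]
    if (is.null(ps) || nrow(ps) == 0L) next
    over <- ps[ps$produced_mM > 10 * dl, , drop = FALSE]
    for (j in seq_len(nrow(over))) {
      flag_rows[[length(flag_rows) + 1L]] <- data.frame(
        flag = "control_activity", microcosm_id = id,
        day = over$day[j], value = over$produced_mM[j])
    }
  }
  flags <- if (length(flag_rows) > 0L) do.call(rbind, flag_rows)
           else data.frame(flag = character(0), microcosm_id = character(0),
                           day = numeric(0), value = numeric(0))
  rownames(flags) <- NULL

  structure(list(
    produced = produced_df,
    rates = rates,
    sulfate = sulfate_df,
    electron_balance = eb,
    co2_final_mM = co2_final_mM,
    oil_consumed_mg = oil_mg,
    flags = flags,
    warnings = warns,
    config = config,
    phase_break = phase_break,
    version = as.character(utils::packageVersion("rsil"))
  ), class = "rsil_report")
}

#' @export
print.rsil_report <- function(x, ...) {
  cat("RSIL analysis report (rsil ", x$version, ")\n", sep = "")
  pooled <- x$rates[x$rates$microcosm_id == "pooled" &
                      x$rates$treatment == "live", , drop = FALSE]
  for (j in seq_len(nrow(pooled))) {
    cat(sprintf("  pooled live, days %g-%g [%s, %s]: %.4g %s\n",
                pooled$interval_start_day[j], pooled$interval_end_day[j],
                pooled$method[j], pooled$basis[j], pooled$value[j],
                pooled$units[j]))
  }
  if (!is.null(x$electron_balance)) {
    cat(sprintf("  electron fraction to sulfate: %.3f, to biomass: %.3f\n",
                x$electron_balance$fraction_to_sulfate,
                x$electron_balance$fraction_to_biomass))
  }
  if (is.finite(x$oil_consumed_mg)) {
    cat(sprintf("  oil consumed: %.3g mg\n", x$oil_consumed_mg))
  }
  if (nrow(x$flags) > 0L) cat("  flags:", nrow(x$flags), "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' Embeds the configuration and package version for provenance; key order
#' is fixed so identical analyses produce byte-identical files.
#'
#' @param report An `rsil_report` from [run_analysis()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "rsil_report"))
  out <- list(
    version = report$version,
    config = unclass(report$config),
    phase_break = report$phase_break,
    rates = report$rates,
    sulfate = report$sulfate,
    electron_balance = if (is.null(report$electron_balance)) NULL
                       else unclass(report$electron_balance),
    co2_final_mM = report$co2_final_mM,
    oil_consumed_mg = report$oil_consumed_mg,
    produced = report$produced,
    flags = report$flags,
    warnings = report$warnings)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' Write the tidy rate table of a report to CSV
#'
#' @inheritParams write_report_json
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rates_csv <- function(report, path) {
  stopifnot(inherits(report, "rsil_report"))
  utils::write.csv(report$rates, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Write the flag table of a report to CSV
#'
#' @inheritParams write_report_json
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flags_csv <- function(report, path) {
  stopifnot(inherits(report, "rsil_report"))
  utils::write.csv(report$flags, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}
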