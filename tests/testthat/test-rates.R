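test_that("rate estimators recover endpoint and OLS slopes", {
  s <- data.frame(day = c(0, 857), produced_mM = c(0, 8.31))
  r <- estimate_rate(s)
  expect_equal(r$value, 8.31 / 857 * 365, tolerance = 1e-12)
  expect_equal(r$value, 3.539, tolerance = 1e-3)
  expect_identical(r$units, "mM/yr")

  flat <- data.frame(day = c(0, 100, 200), produced_mM = c(1, 1, 1))
  expect_equal(estimate_rate(flat)$value, 0)
  expect_equal(estimate_rate(flat, method = "ols")$value, 0)

  line <- data.frame(day = 0:10, produced_mM = 0.05 * (0:10))
  expect_equal(estimate_rate(line, method = "ols")$value, 18.25,
               tolerance = 1e-10)
  # endpoint and OLS coincide on noiseless linear data
  expect_equal(estimate_rate(line, method = "endpoint")$value,
               estimate_rate(line, method = "ols")$value, tolerance = 1e-10)

  # interval subsetting and insufficient data
  expect_equal(estimate_rate(line, interval = c(0, 5))$value, 18.25,
               tolerance = 1e-10)
  expect_error(estimate_rate(line, interval = c(20, 30)),
               class = "rsil_insufficient_data")
})

test_that("replicate averaging reproduces the pooled early rate", {
  iv <- c(0, 122)
  rs <- lapply(c(18.17, 15.27, 19.29, 17.61), rate_estimate,
               units = "mM/yr", interval = iv)
  m <- mean_replicate_rate(rs)
  expect_equal(m$value, mean(c(18.17, 15.27, 19.29, 17.61)), tolerance = 1e-12)
  expect_equal(m$value, 17.585, tolerance = 1e-12)
  expect_equal(m$sd, stats::sd(c(18.17, 15.27, 19.29, 17.61)), tolerance = 1e-12)
  expect_identical(m$n, 4L)

  single <- mean_replicate_rate(rs[1])
  expect_equal(single$value, 18.17)
  expect_equal(mean_replicate_rate(list(
    rate_estimate(1, "mM/yr", iv), rate_estimate(3, "mM/yr", iv)))$value, 2)

  expect_error(mean_replicate_rate(list(
    rate_estimate(1, "mM/yr", iv), rate_estimate(1, "mmol/yr", iv))),
    class = "rsil_unit_mismatch")
  expect_error(mean_replicate_rate(list(
    rate_estimate(1, "mM/yr", iv), rate_estimate(1, "mM/yr", c(0, 857)))),
    class = "rsil_invalid_interval")
})

test_that("amount conversion and the three normalizations close algebraically", {
  cfg <- microcosm_config()
  iv <- c(0, 857)
  conc <- rate_estimate(3.539, "mM/yr", iv)
  amt <- to_amount_rate(conc, cfg)
  expect_equal(amt$value, 0.3539, tolerance = 1e-12)
  expect_identical(amt$units, "mmol/yr")
  expect_equal(to_amount_rate(rate_estimate(17.6, "mM/yr", iv), cfg)$value,
               1.76, tolerance = 1e-12)
  expect_error(to_amount_rate(amt, cfg), class = "rsil_unit_mismatch")

  r035 <- rate_estimate(0.35, "mmol/yr", iv)
  per_g <- normalize_rate(r035, cfg, "per_g_oil")
  expect_equal(per_g$value, 0.35 / 0.33, tolerance = 1e-12)
  expect_equal(per_g$value, 1.061, tolerance = 1e-3)
  per_ch2 <- normalize_rate(r035, cfg, "per_mol_ch2")
  expect_equal(per_ch2$value, 0.35 / (0.33 / 14.0266), tolerance = 1e-12)
  expect_equal(per_ch2$value, 14.88, tolerance = 1e-3)
  per_owc <- normalize_rate(rate_estimate(0.354, "mmol/yr", iv), cfg,
                            "per_owc_area")
  expect_equal(per_owc$value, 0.354 * 14.0266 / 1000 / 16.61e-4,
               tolerance = 1e-12)
  expect_equal(per_owc$value, 2.99, tolerance = 1e-3)
  expect_error(normalize_rate(conc, cfg, "per_g_oil"),
               class = "rsil_unit_mismatch")

  # unit algebra closes: undoing each normalization recovers the input
  set.seed(11)
  for (v in stats::runif(20, 0, 5)) {
    r <- rate_estimate(v, "mmol/yr", iv)
    expect_equal(normalize_rate(r, cfg, "per_g_oil")$value * cfg$oil_mass_g,
                 v, tolerance = 1e-12)
    expect_equal(normalize_rate(r, cfg, "per_mol_ch2")$value *
                   (cfg$oil_mass_g / cfg$ch2_molar_mass), v, tolerance = 1e-12)
    expect_equal(normalize_rate(r, cfg, "per_owc_area")$value *
                   cfg$owc_area_m2 * 1000 / cfg$ch2_molar_mass, v,
                 tolerance = 1e-12)
  }
})

test_that("sulfate accounting matches endpoint arithmetic", {
  cfg <- microcosm_config()
  s <- data.frame(day = c(0, 857), sulfate_mM = c(20.6, 15.2))
  out <- sulfate_reduced(s, cfg)
  expect_equal(out$total_mmol, 0.54, tolerance = 1e-12)
  expect_equal(out$rate$value, 0.54 / 857 * 365, tolerance = 1e-12)
  expect_equal(out$rate$value, 0.230, tolerance = 1e-3)
  expect_identical(out$rate$units, "mmolSO4/yr")
  expect_false(out$flagged_increase)

  none <- sulfate_reduced(data.frame(day = c(0, 100),
                                     sulfate_mM = c(20, 20)), cfg)
  expect_equal(none$total_mmol, 0)
  inc <- sulfate_reduced(data.frame(day = c(0, 100),
                                    sulfate_mM = c(20, 21)), cfg)
  expect_true(inc$flagged_increase)
  expect_error(sulfate_reduced(data.frame(day = 0, sulfate_mM = 20), cfg),
               class = "rsil_insufficient_data")
})

test_that("electron balance partitions donor electrons correctly", {
  cfg <- microcosm_config()
  eb <- electron_balance(8.3, 5.4, cfg)
  expect_equal(eb$fraction_to_sulfate, (5.4 * 8) / (8.3 * 6), tolerance = 1e-12)
  expect_equal(eb$fraction_to_sulfate, 0.867, tolerance = 1e-3)
  expect_equal(eb$fraction_to_sulfate + eb$fraction_to_biomass, 1)
  expect_false(eb$flagged_inconsistent)

  expect_equal(electron_balance(5, 0, cfg)$fraction_to_sulfate, 0)
  expect_equal(electron_balance(8, 6, cfg)$fraction_to_sulfate, 1)

  # acceptor exceeding donor, or acceptor without donor, is flagged
  expect_true(electron_balance(1, 6, cfg)$flagged_inconsistent)
  expect_true(electron_balance(0, 1, cfg)$flagged_inconsistent)
  expect_false(electron_balance(0, 0, cfg)$flagged_inconsistent)

  set.seed(5)
  for (i in 1:25) {
    co2 <- stats::runif(1, 0.1, 20)
    so4 <- stats::runif(1, 0, co2 * 6 / 8)
    e <- electron_balance(co2, so4, cfg)
    expect_equal(e$fraction_to_sulfate + e$fraction_to_biomass, 1)
  }
})

test_that("oil mass consumed is the CH2 molar-mass conversion", {
  cfg <- microcosm_config()
  expect_equal(oil_consumed_mass(0.83, cfg), 0.83 * 14.0266, tolerance = 1e-12)
  expect_equal(oil_consumed_mass(0.83, cfg), 11.64, tolerance = 1e-3)
  expect_equal(oil_consumed_mass(0, cfg), 0)
  expect_equal(oil_consumed_mass(1, cfg), 14.0266)
})

test_that("headline chain reproduces its own unrounded arithmetic", {
  cfg <- microcosm_config()
  chain <- transparent_chain(8.31, 857, 20.6, 15.2, cfg)
  expect_equal(chain$total_co2_mmol, 0.831, tolerance = 1e-12)
  expect_equal(chain$overall_rate_mmol_yr, 0.831 / 857 * 365, tolerance = 1e-12)
  expect_equal(chain$rate_per_g_oil_mmol_g_yr,
               chain$overall_rate_mmol_yr / 0.33, tolerance = 1e-12)
  expect_equal(chain$sulfate_reduced_mmol, 0.54, tolerance = 1e-12)
  expect_equal(chain$fraction_to_sulfate, (5.4 * 8) / (8.31 * 6),
               tolerance = 1e-12)
  expect_equal(chain$oil_consumed_mg, 0.831 * 14.0266, tolerance = 1e-12)
})
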