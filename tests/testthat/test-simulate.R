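test_that("simulation is deterministic and replicate streams are stable", {
  p <- simulation_params(seed = 1)
  a <- simulate_microcosms(p)
  b <- simulate_microcosms(p)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$truth$series, b$truth$series)

  c <- simulate_microcosms(simulation_params(seed = 2))
  expect_false(identical(a$measurements, c$measurements))

  # adding a live replicate leaves existing replicate streams untouched
  wide <- simulate_microcosms(simulation_params(seed = 1, n_live = 5))
  keep <- wide$measurements$microcosm_id %in% unique(a$measurements$microcosm_id)
  sub <- wide$measurements[keep, ]
  rownames(sub) <- NULL
  expect_identical(sub, a$measurements)
})

test_that("noiseless simulation reproduces the configured world exactly", {
  p <- simulation_params(seed = 1, sigma_delta = 0, replicate_cv = 0)
  sim <- simulate_microcosms(p)
  cfg <- microcosm_config()

  # truth invariants
  tr <- sim$truth$series
  for (id in unique(tr$microcosm_id)) {
    s <- tr[tr$microcosm_id == id, ]
    expect_true(all(diff(s$cum_co2_mM) >= 0))
    expect_true(all(diff(s$sulfate_mM) <= 0))
    expect_true(all(diff(s$delta_true) <= 0))  # label can only be diluted
  }

  # cumulative CO2 at the end of the schedule hits the target total
  live1 <- tr[tr$microcosm_id == "live_1", ]
  expect_equal(live1$cum_co2_mM[nrow(live1)], p$total_co2_mM, tolerance = 1e-9)
  expect_equal(live1$cum_co2_mM[live1$day == 122], 17.6 * 122 / 365,
               tolerance = 1e-12)

  # analyzed early rate equals the configured rate to well under 0.1%
  rep <- run_analysis(sim$measurements, cfg)
  early <- rep$rates[rep$rates$microcosm_id == "pooled" &
                       rep$rates$treatment == "live" &
                       rep$rates$interval_end_day == 122, ]
  expect_equal(early$value, 17.6, tolerance = 1e-6)

  # electron conservation by construction: fraction to sulfate is exactly
  # 1 - biomass_fraction
  expect_equal(rep$electron_balance$fraction_to_sulfate,
               1 - p$biomass_fraction, tolerance = 1e-9)

  # controls at zero rate sit exactly on the buffer signature
  ctrl <- sim$measurements[sim$measurements$treatment == "autoclaved", ]
  expect_equal(ctrl$delta13c_permil,
               rep(atom_fraction_to_delta(0.10), nrow(ctrl)), tolerance = 1e-9)
  expect_equal(unique(round(ctrl$cells_per_ml)), 1.8e5)
})

test_that("a dead experiment produces nothing", {
  p <- simulation_params(seed = 3, early_rate = 0, late_rate = 0,
                         sigma_delta = 0, replicate_cv = 0)
  sim <- simulate_microcosms(p)
  expect_true(all(sim$truth$series$cum_co2_mM == 0))
  expect_equal(sim$measurements$delta13c_permil,
               rep(atom_fraction_to_delta(0.10), nrow(sim$measurements)),
               tolerance = 1e-9)
})

test_that("sulfate exhaustion aborts the simulation naming the day", {
  p <- simulation_params(seed = 1, early_rate = 200, late_rate = 200,
                         sulfate_initial = 5, replicate_cv = 0)
  expect_error(simulate_microcosms(p), "day",
               class = "rsil_simulation_infeasible")
})

test_that("parameter validation rejects malformed worlds", {
  expect_error(simulation_params(schedule = c(10, 20)),
               class = "rsil_invalid_params")
  expect_error(simulation_params(schedule = c(0, 30, 30)),
               class = "rsil_invalid_params")
  expect_error(simulation_params(early_rate = -1),
               class = "rsil_invalid_params")
  expect_error(simulation_params(biomass_fraction = 1.2),
               class = "rsil_invalid_params")
})

test_that("parameter recovery is exact without noise and unbiased with it", {
  cfg <- microcosm_config()
  exact <- parameter_recovery_trial(
    simulation_params(seed = 9, sigma_delta = 0, replicate_cv = 0),
    cfg, n_seeds = 3)
  expect_equal(exact$summary$relative_bias, 0, tolerance = 1e-6)
  expect_equal(exact$summary$rmse, 0, tolerance = 1e-6)
  expect_equal(exact$summary$mean_fraction_to_sulfate,
               exact$summary$target_fraction_to_sulfate, tolerance = 1e-9)

  noisy <- parameter_recovery_trial(simulation_params(seed = 100), cfg,
                                    n_seeds = 40)
  expect_lt(abs(noisy$summary$relative_bias), 0.05)
  expect_equal(noisy$summary$mean_fraction_to_sulfate,
               noisy$summary$target_fraction_to_sulfate, tolerance = 0.02)
})

test_that("sub-detection-limit activity is indistinguishable from controls", {
  cfg <- microcosm_config()
  # noise of 0.5 permil in delta corresponds to ~4.5e-4 atom% near the
  # buffer signature; the implied detectable rate over 122 days is ~1e-3
  # mM/yr, so a 5e-4 mM/yr world sits below the detection limit.
  n_reject <- 0L
  n_seeds <- 60L
  for (s in seq_len(n_seeds)) {
    p <- simulation_params(seed = 2000 + s, early_rate = 5e-4,
                           late_rate = 5e-4, replicate_cv = 0)
    sim <- simulate_microcosms(p, cfg)
    rep <- run_analysis(sim$measurements, cfg)
    per_rep <- rep$rates[rep$rates$microcosm_id != "pooled" &
                           rep$rates$interval_end_day == 122, ]
    live <- per_rep$value[per_rep$treatment == "live"]
    ctrl <- per_rep$value[per_rep$treatment == "autoclaved"]
    pval <- stats::t.test(live, ctrl)$p.value
    if (pval < 0.05) n_reject <- n_reject + 1L
  }
  expect_gte((n_seeds - n_reject) / n_seeds, 0.9)
})

test_that("first-order kinetics saturate at the configured total", {
  p <- simulation_params(seed = 4, sigma_delta = 0, replicate_cv = 0,
                         kinetics = "first_order",
                         schedule = c(0, 30, 60, 91, 122, 857, 5000))
  sim <- simulate_microcosms(p)
  s <- sim$truth$series[sim$truth$series$microcosm_id == "live_1", ]
  expect_true(all(diff(s$cum_co2_mM) > 0))
  expect_lt(abs(s$cum_co2_mM[s$day == 5000] - p$total_co2_mM), 0.01)
  # closed form with initial slope early_rate: cum(t) = Cmax(1 - e^(-kt)),
  # k = early_rate / (365 Cmax); saturation keeps it below the linear bound
  k <- 17.6 / 365 / p$total_co2_mM
  expect_equal(s$cum_co2_mM, p$total_co2_mM * (1 - exp(-k * s$day)),
               tolerance = 1e-12)
  expect_true(all(s$cum_co2_mM[-1] < 17.6 * s$day[-1] / 365))
})
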