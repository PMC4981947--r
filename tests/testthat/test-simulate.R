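test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(n_weeks = 1), class = "bloomkit_config_error")
  expect_error(sim_config(eta = -1), class = "bloomkit_config_error")
  expect_error(sim_config(d0 = -0.1), class = "bloomkit_config_error")
  expect_error(sim_config(pulse_prob = 1.5), class = "bloomkit_config_error")
  expect_error(sim_config(salinity_range = c(10, 10)), class = "bloomkit_config_error")
})

test_that("environment generation is deterministic and honours degenerate settings", {
  cfg <- sim_config(seed = 5)
  e1 <- simulate_environment(cfg)
  e2 <- simulate_environment(cfg)
  expect_identical(e1, e2)

  # AR(1) coefficient 0, noise sd 0: temperature pinned at the mean
  cfg0 <- sim_config(temp_ar1 = 0, temp_sd = 0, seed = 5)
  e0 <- simulate_environment(cfg0)
  expect_equal(e0$temp_c, rep(cfg0$temp_mean, cfg0$n_weeks))

  # pulses disabled and baseline dispersion zero: no PM exceedances
  cfgp <- sim_config(pulse_prob = 0, pm_sdlog = 0, seed = 5)
  ep <- simulate_environment(cfgp)
  expect_equal(sum(ep$pm_mg_l > cfgp$pm_threshold), 0)
  expect_length(attr(ep, "pulse_weeks"), 0)

  expect_true(all(e1$salinity >= cfg$salinity_range[1]))
  expect_true(all(e1$salinity <= cfg$salinity_range[2]))
})

test_that("balanced birth and death with no hatching holds the population constant", {
  b_const <- log(1 + 0.35 / 1)  # egg ratio 0.35, D_E = 1 at 25 C
  cfg <- noisefree_config(n_lakes = 1, n_weeks = 12, eta = 0, d0 = b_const,
                          temp_ar1 = 0)
  sim <- simulate_lakes(cfg)
  N <- sim$lakes[[1]]$species_density_B_dimidiatus
  expect_equal(N, rep(N[1], 12), tolerance = 1e-10)
})

test_that("zero death and a doubling egg ratio give exact weekly doubling", {
  E_dbl <- 2^(1 / 7) - 1  # b = ln(1 + E) = ln(2)/7 per day
  cfg <- noisefree_config(n_lakes = 1, n_weeks = 10, eta = 0, d0 = 0,
                          egg_mean = E_dbl, temp_ar1 = 0)
  sim <- simulate_lakes(cfg)
  N <- sim$lakes[[1]]$species_density_B_dimidiatus
  expect_equal(N[-1] / N[-10], rep(2, 9), tolerance = 1e-10)
})

test_that("hatch pulses appear exactly one lag after every PM exceedance", {
  cfg <- sim_config(n_lakes = 1, seed = 21)
  sim <- simulate_lakes(cfg)
  tr <- sim$truth[[1]]
  pm <- sim$lakes[[1]]$pm_mg_l
  for (sp in cfg$species) {
    L <- tr$lag_by_species[[sp]]
    w <- tr$hatch[[sp]]$weeks
    expect_true(all(pm[w - L] > cfg$pm_threshold))
    expected <- tr$pm_exceed_weeks + L
    expect_setequal(w, expected[expected <= cfg$n_weeks])
  }
})

test_that("multi-lake datasets have the right shape, positivity and independence", {
  cfg <- sim_config(n_lakes = 7, n_weeks = 60, seed = 9)
  sim <- simulate_lakes(cfg)
  expect_length(sim$lakes, 7)
  expect_true(all(vapply(sim$lakes, nrow, numeric(1)) == 60))
  stacked <- as_meta_df(sim)
  expect_equal(nrow(stacked), 7 * 60)
  dens_cols <- paste0("species_density_", cfg$species)
  expect_true(all(as.matrix(stacked[, dens_cols]) >= 0))

  # different lakes are different realizations
  expect_false(identical(sim$lakes[[1]]$pm_mg_l, sim$lakes[[2]]$pm_mg_l))

  # adding lakes never perturbs earlier lakes
  cfg2 <- sim_config(n_lakes = 2, n_weeks = 60, seed = 9)
  sim2 <- simulate_lakes(cfg2)
  expect_identical(sim2$lakes[[1]], sim$lakes[[1]])
})

test_that("full simulation is byte-identical under the same seed", {
  cfg <- sim_config(n_lakes = 2, n_weeks = 25, seed = 77)
  s1 <- simulate_lakes(cfg)
  s2 <- simulate_lakes(cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_timeseries_csv(s1$lakes[[2]], f1)
  write_timeseries_csv(s2$lakes[[2]], f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$truth, s2$truth)
})

test_that("injected phytoplankton breakpoints are recorded in the truth ledger", {
  cfg <- sim_config(n_lakes = 1, seed = 2)
  sim <- simulate_lakes(cfg)
  expect_equal(sim$truth[[1]]$breakpoints$small_algae, 11)
  expect_equal(sim$truth[[1]]$breakpoints$filamentous, 13)
  expect_true(all(diff(unlist(sim$truth[[1]]$breakpoints)) > 0))
})
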