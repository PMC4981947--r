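test_that("growth rate matches the log-difference closed form and guards its domain", {
  expect_equal(growth_rate(100, 100, 0, 7), 0)
  expect_equal(growth_rate(100, 200, 0, 7), log(2) / 7)
  expect_equal(growth_rate(c(100, 50), c(200, 25), 0, 7),
               c(log(2), -log(2)) / 7)
  expect_error(growth_rate(0, 100, 0, 7), class = "bloomkit_rate_error")
  expect_error(growth_rate(100, 0, 0, 7), class = "bloomkit_rate_error")
  expect_error(growth_rate(100, 200, 7, 7), class = "bloomkit_interval_error")
})

test_that("egg development time is anchored, monotone decreasing, and Q10-consistent", {
  expect_equal(egg_development_time(25), 1.0)
  expect_gt(egg_development_time(20), egg_development_time(30))
  temps <- seq(10, 34, by = 2)
  expect_true(all(diff(egg_development_time(temps)) < 0))
  # the anchored Q10 form fixes the decade ratio exactly
  expect_equal(egg_development_time(15) / egg_development_time(25), 2.5)
  expect_equal(egg_development_time(22, Q10 = 3) / egg_development_time(32, Q10 = 3), 3)
  expect_error(egg_development_time(5), class = "bloomkit_domain_error")
  expect_error(egg_development_time(40), class = "bloomkit_domain_error")
})

test_that("egg-ratio birth rate matches closed forms and stays non-negative", {
  expect_equal(birth_rate(0, 100, D_E = 1), 0)
  expect_equal(birth_rate(100, 100, D_E = 1), log(2))
  expect_equal(birth_rate(50, 100, D_E = 2), log(1.25))
  expect_equal(birth_rate(100, 100, D_E = 1, c_E = 2), log(3))
  expect_error(birth_rate(10, 0, D_E = 1), class = "bloomkit_rate_error")

  set.seed(41)
  for (i in 1:50) {
    NE <- runif(1, 0, 500); NF <- runif(1, 1, 500); DE <- runif(1, 0.5, 3)
    b <- birth_rate(NE, NF, DE)
    expect_gte(b, 0)
    # scale invariance: b depends on the egg ratio only
    k <- runif(1, 0.1, 20)
    expect_equal(birth_rate(k * NE, k * NF, DE), b)
  }
})

test_that("death rate is the exact b - r difference and flags negative values", {
  expect_equal(as.numeric(death_rate(0.3, 0.3)), 0)
  d <- death_rate(0.3, 0.6)
  expect_equal(as.numeric(d), -0.3)
  expect_true(attr(d, "recruitment_flag"))
  d2 <- death_rate(c(0.5, 0.2), c(0.1, 0.4))
  expect_equal(attr(d2, "recruitment_flag"), c(FALSE, TRUE))
})

test_that("lifespan-implied death rate presents at two decimals", {
  d <- lifespan_death_rate(9.5)
  expect_equal(as.numeric(d), 1 / 9.5)
  expect_identical(attr(d, "presented"), "0.11")
  expect_equal(as.numeric(lifespan_death_rate(1)), 1)
  expect_lt(as.numeric(lifespan_death_rate(1e6)), 1e-5)
  expect_error(lifespan_death_rate(0), class = "bloomkit_domain_error")
})

test_that("demographic series does interval bookkeeping and breaks at zero densities", {
  ts <- toy_series(10)
  dem <- demographic_series(ts, "B_dimidiatus")
  expect_equal(nrow(dem), 9)
  expect_equal(dem$r, rep(log(2) / 7, 9))
  expect_equal(dem$d, dem$b - dem$r)

  const <- toy_series(6, N = rep(200, 6))
  dc <- demographic_series(const, "B_dimidiatus")
  expect_equal(dc$r, rep(0, 5))
  expect_equal(dc$d, dc$b)

  holey <- toy_series(6, N = c(100, 200, 0, 0, 100, 200))
  dh <- demographic_series(holey, "B_dimidiatus")
  expect_true(all(is.na(dh$r[2:4])))
  expect_true(all(is.na(dh$d[2:4])))
  expect_false(anyNA(dh$r[c(1, 5)]))

  expect_error(demographic_series(toy_series(1), "B_dimidiatus"),
               class = "bloomkit_insufficient_data")
  expect_error(demographic_series(ts, "H_missing"), class = "bloomkit_data_error")
})

test_that("egg-ratio demography reproduces the generator's birth rates exactly", {
  cfg <- sim_config(n_lakes = 1, n_weeks = 30, seed = 11)
  sim <- simulate_lakes(cfg)
  dem <- demographic_series(sim$lakes[[1]], "B_dimidiatus")
  expect_equal(dem$b, sim$truth[[1]]$birth_rates[1:29, 1], tolerance = 1e-12)
})

test_that("with hatching off and noise-free rates, estimated d recovers the generator d0", {
  cfg <- noisefree_config(n_lakes = 1, n_weeks = 30, eta = 0, seed = 3)
  sim <- simulate_lakes(cfg)
  dem <- demographic_series(sim$lakes[[1]], "B_dimidiatus")
  expect_equal(mean(dem$d), cfg$d0, tolerance = 1e-10)
  expect_true(all(dem$d >= 0))
})
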