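test_that("the onset rule requires both the jump and the threshold", {
  s <- data.frame(total_biomass = c(6, 6, 20, 22))
  det <- detect_bloom_onsets(s, bloom_rule(mode = "fixed"))
  expect_equal(det$events$index, 3)
  expect_equal(as.character(det$events$class), "8-20")
  expect_equal(det$onset, c(NA, 0L, 1L, 0L))

  expect_equal(nrow(detect_bloom_onsets(
    data.frame(total_biomass = rep(5, 6)), bloom_rule(mode = "fixed"))$events), 0)

  # a 250% jump that stays under 4 g DM m^-3 is not an onset
  s2 <- data.frame(total_biomass = c(1, 3.5))
  expect_equal(nrow(detect_bloom_onsets(s2, bloom_rule(mode = "fixed"))$events), 0)

  # appearance from zero counts as the strongest possible increase
  s3 <- data.frame(total_biomass = c(0, 5))
  expect_equal(detect_bloom_onsets(s3, bloom_rule(mode = "fixed"))$events$index, 2)
})

test_that("detection matches a brute-force re-application of the rule on fuzzed series", {
  set.seed(14)
  for (i in 1:25) {
    B <- rlnorm(30, log(3), 1)
    B[sample(30, 2)] <- 0  # occasional zero densities
    for (mode in c("fixed", "ci", "either", "both")) {
      det <- detect_bloom_onsets(data.frame(total_biomass = B),
                                 bloom_rule(mode = mode))
      expect_identical(det$onset, brute_onsets(B, mode = mode))
    }
  }
})

test_that("the lake CI threshold follows normal theory on the biomass scale", {
  expect_equal(lake_ci_threshold(rep(3, 5)), 3)
  expect_equal(lake_ci_threshold(c(2, 4, 6), 0.90),
               4 + qnorm(0.95) * 2 / sqrt(3))
  expect_lt(lake_ci_threshold(c(2, 4, 6), 0.90), lake_ci_threshold(c(2, 4, 6), 0.99))
  expect_error(lake_ci_threshold(c(1, 2)), class = "bloomkit_insufficient_data")
})

test_that("covariate standardization pools across lakes; range mode maps to [0, 1]", {
  cfg <- sim_config(n_lakes = 3, n_weeks = 20, seed = 6)
  df <- as_meta_df(simulate_lakes(cfg))
  z <- standardize_covariates(df, c("salinity", "chla_ug_l"))
  expect_equal(mean(z$salinity), 0, tolerance = 1e-12)
  expect_equal(sd(z$chla_ug_l), 1, tolerance = 1e-12)

  r <- standardize_covariates(df, "pm_mg_l", mode = "range")
  expect_equal(range(r$pm_mg_l), c(0, 1))

  df$flat <- 1
  expect_error(standardize_covariates(df, "flat"),
               class = "bloomkit_degenerate_variable")
})

## simulate a stacked multi-lake logistic dataset with known coefficients
logit_dataset <- function(n_lakes = 6, n = 40, beta = c(sal = 0, chla = 0),
                          lake_sd = 0.5, intercept = -2, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_lakes), function(lk) {
    u <- rnorm(1, 0, lake_sd)
    sal <- rnorm(n); chla <- rnorm(n)
    eta <- intercept + u + beta[["sal"]] * sal + beta[["chla"]] * chla
    data.frame(lake_id = lk, sal = sal, chla = chla,
               onset = rbinom(n, 1, plogis(eta)))
  }))
}

test_that("the mixed logit recovers a strong negative salinity effect", {
  dat <- logit_dataset(beta = c(sal = -1.5, chla = 0), seed = 33)
  fit <- fit_bloom_logit(dat, c("sal", "chla"))
  sal_row <- fit$coefficients[fit$coefficients$term == "sal", ]
  expect_lt(sal_row$estimate, 0)
  expect_gt(abs(sal_row$z), 2)
  expect_true(fit$converged)
  # AIC bookkeeping: fixed effects + intercept + random-intercept variance
  expect_equal(fit$AIC, 2 * 4 - 2 * fit$logLik)
})

test_that("without the random effect the fit reduces to plain logistic regression", {
  dat <- logit_dataset(beta = c(sal = -1, chla = 0.5), lake_sd = 0, seed = 12)
  fit <- fit_bloom_logit(dat, c("sal", "chla"), random = FALSE)
  ref <- glm(onset ~ sal + chla, binomial(), dat)
  expect_equal(coef(fit), coef(ref), tolerance = 1e-10)
  expect_equal(fit$ranef_var, 0)
  expect_equal(fit$AIC, AIC(ref))
})

test_that("complete separation is reported as a diagnosed non-converged fit", {
  dat <- data.frame(lake_id = rep(1:2, each = 10),
                    x = rep(c(-1, 1), each = 10),
                    onset = rep(c(0, 1), each = 10))
  fit <- fit_bloom_logit(dat, "x", random = FALSE)
  expect_false(fit$converged)
  expect_true(nzchar(fit$diagnostic))
})

test_that("all-subsets AIC selection enumerates 2^k models and finds true structure", {
  dat <- logit_dataset(beta = c(sal = -2, chla = 0), lake_sd = 0, seed = 4)
  dat$noise1 <- rnorm(nrow(dat)); dat$noise2 <- rnorm(nrow(dat))
  sel <- select_model_aic(dat, c("sal", "chla", "noise1", "noise2"), random = FALSE)
  expect_equal(nrow(sel$table), 16)
  expect_true("sal" %in% sel$best_predictors)

  # under the null, noise predictors rarely beat the intercept-only model
  wins <- sum(vapply(1:20, function(s) {
    d0 <- logit_dataset(n_lakes = 4, n = 30, lake_sd = 0, seed = 100 + s)
    s0 <- select_model_aic(d0, c("sal", "chla"), random = FALSE)
    length(s0$best_predictors) == 0
  }, logical(1)))
  expect_gte(wins, 12)
})

test_that("the paired pre-bloom contrast matches the textbook formula", {
  df <- data.frame(fil = c(0.2, 0.5, 0.1, 0.6, 0.3, 0.8))
  ev <- data.frame(lake_id = NA, index = c(2, 4, 6))
  ctr <- prebloom_contrast(df, ev, "fil")
  dif <- c(0.3, 0.5, 0.5)
  t_hand <- mean(dif) / (sd(dif) / sqrt(3))
  expect_equal(ctr$t, t_hand)
  expect_equal(ctr$p, 2 * pt(-abs(t_hand), 2))
  expect_equal(ctr$n_pairs, 3)

  same <- data.frame(fil = rep(0.4, 6))
  c0 <- prebloom_contrast(same, ev, "fil")
  expect_equal(c0$t, 0); expect_equal(c0$p, 1); expect_true(c0$degenerate)

  shift <- data.frame(fil = rep(c(0.2, 0.4), 3))
  c1 <- prebloom_contrast(shift, ev, "fil")
  expect_equal(c1$p, 0); expect_true(c1$degenerate)
})

test_that("bloom frequency is the inverse event rate over monitored months", {
  f <- bloom_frequency(187.2, 36)
  expect_equal(f$months_per_bloom, 5.2)
  expect_equal(bloom_frequency(1, 1)$months_per_bloom, 1)
  expect_equal(bloom_frequency(374.4, 36)$months_per_bloom, 10.4)
  z <- bloom_frequency(12, 0)
  expect_true(z$no_events)
  expect_equal(z$months_per_bloom, Inf)
})
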