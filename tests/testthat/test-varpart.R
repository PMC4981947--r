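test_that("RDA recovers a perfect linear map and matches the per-column decomposition", {
  set.seed(3)
  X <- matrix(rnorm(40), 20)
  B <- matrix(runif(6, -1, 1), 2)
  Yp <- X %*% B
  f <- rda(Yp, X)
  expect_equal(f$R2, 1, tolerance = 1e-12)
  expect_equal(sum(f$residuals^2), 0, tolerance = 1e-10)

  Y <- Yp + matrix(rnorm(60), 20)
  f2 <- rda(Y, X)
  expect_equal(f2$R2, lm_r2(Y, X), tolerance = 1e-12)
  expect_equal(f2$R2_adj, 1 - (1 - f2$R2) * 19 / (20 - 2 - 1))
})

test_that("pure-noise constraints have near-zero adjusted R2 on average", {
  set.seed(15)
  adj <- vapply(1:100, function(i) {
    rda(matrix(rnorm(60), 20), matrix(rnorm(20), 20))$R2_adj
  }, numeric(1))
  expect_lt(abs(mean(adj)), 0.03)
})

test_that("RDA agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(10)
  Y <- matrix(rnorm(60), 20); colnames(Y) <- paste0("sp", 1:3)
  X <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
  Z <- data.frame(z1 = rnorm(20))
  f <- rda(Y, X)
  v <- vegan::RsquareAdj(vegan::rda(Y ~ x1 + x2, data = X))
  expect_equal(f$R2, v$r.squared, tolerance = 1e-10)
  expect_equal(f$R2_adj, v$adj.r.squared, tolerance = 1e-10)

  pf <- partial_rda(Y, X, Z)
  vp <- vegan::varpart(Y, X, Z)
  expect_equal(pf$R2_cond_adj, vp$part$indfract$Adj.R.squared[1], tolerance = 1e-10)
})

test_that("rank-deficient predictors raise a collinearity error naming columns", {
  X <- cbind(a = rnorm(15), b = rnorm(15))
  X <- cbind(X, c = X[, 1] + X[, 2])
  err <- tryCatch(rda(matrix(rnorm(30), 15), X), error = identity)
  expect_s3_class(err, "bloomkit_collinearity_error")
  expect_match(conditionMessage(err), "c")
})

test_that("partial RDA reduces correctly in its degenerate configurations", {
  set.seed(20)
  Y <- matrix(rnorm(60), 20); X <- matrix(rnorm(40), 20); Z <- matrix(rnorm(20), 20)
  p0 <- partial_rda(Y, X, NULL)
  expect_equal(p0$R2_cond, rda(Y, X)$R2, tolerance = 1e-12)

  # focal variables inside the span of the conditioning set explain nothing
  Zbig <- cbind(z = Z, extra = rnorm(20))
  Xin <- cbind(x_in_z = 2 * Z[, 1])
  expect_lt(partial_rda(Y, Xin, Zbig)$R2_cond, 1e-10)
})

test_that("the residualization route equals the nested-model difference (oracle)", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(15:30, 1)
    m <- sample(1:3, 1); q <- sample(1:2, 1)
    Y <- matrix(rnorm(n * 3), n)
    X <- matrix(rnorm(n * m), n)
    Z <- matrix(rnorm(n * q), n)
    pf <- partial_rda(Y, X, Z)
    oracle <- lm_r2(Y, cbind(Z, X)) - lm_r2(Y, Z)
    expect_equal(pf$R2_cond, oracle, tolerance = 1e-10)
  }
})

test_that("variance partitioning conserves the unadjusted fractions exactly", {
  set.seed(44)
  for (i in 1:15) {
    n <- sample(18:30, 1)
    Y <- matrix(rnorm(n * 3), n)
    X1 <- matrix(rnorm(n * 2), n)
    X2 <- matrix(rnorm(n * 2), n)
    vp <- variance_partition(Y, X1, X2)
    expect_equal(sum(vp$fractions), 1, tolerance = 1e-10)
  }
})

test_that("shared and unique fractions behave for duplicated and noise predictor sets", {
  set.seed(50)
  Y <- matrix(rnorm(75), 25)
  X1 <- matrix(rnorm(50), 25)
  vp_dup <- variance_partition(Y, X1, X1 + 0)  # fully shared information
  expect_equal(vp_dup$fractions[["a"]], 0, tolerance = 1e-10)
  expect_equal(vp_dup$fractions[["c"]], 0, tolerance = 1e-10)
  expect_gt(vp_dup$fractions[["b"]], 0)

  ## X2 pure noise: its unique adjusted fraction is near zero, and the X1
  ## fraction approaches the plain adjusted R2 of rda(Y, X1)
  Ystr <- X1 %*% matrix(c(1, -1, 0.5, 0.2, 0.3, -0.5), 2) + matrix(rnorm(75), 25)
  c_adj <- vapply(1:40, function(i) {
    vp <- variance_partition(Ystr, X1, matrix(rnorm(25), 25))
    vp$fractions_adj[["c"]]
  }, numeric(1))
  expect_lt(abs(mean(c_adj)), 0.03)
})

test_that("permutation p-values are seeded and attain the exact minimum under perfect fit", {
  set.seed(61)
  X <- matrix(rnorm(30), 15)
  Y <- X %*% matrix(c(1, 2, -1, 0.5, 0.3, 1), 2)
  p <- permutation_test(Y, X, n_perm = 199, seed = 9)
  expect_equal(p$p, 1 / 200)
  p2 <- permutation_test(Y, X, n_perm = 199, seed = 9)
  expect_identical(p, p2)
  expect_warning(permutation_test(Y, X, n_perm = 50, seed = 1), "resolution")
})

test_that("the lag scan is consistent at lag zero and keeps n constant", {
  cfg <- sim_config(n_lakes = 1, seed = 71)
  lk <- simulate_lakes(cfg)$lakes[[1]]
  Y <- as.matrix(lk[, paste0("species_biomass_", cfg$species)])
  X1 <- as.matrix(lk[, c("temp_c", "salinity")])
  X2 <- as.matrix(lk[, "pm_mg_l", drop = FALSE])
  sc <- lagged_varpart(Y, X1, X2, lags = 0:7, n_perm = 99, seed = 5)
  expect_equal(length(unique(sc$table$n)), 1)
  expect_equal(sc$table$n[1], nrow(Y) - 7)

  win <- (7 + 1):nrow(Y)
  vp0 <- variance_partition(Y[win, ], X1[win, ], X2[win, , drop = FALSE])
  expect_equal(sc$table$a[1], vp0$fractions[["a"]], tolerance = 1e-12)
  expect_equal(sc$table$c[1], vp0$fractions[["c"]], tolerance = 1e-12)
  expect_true(all(sc$table$p_a_bonf >= sc$table$p_a - 1e-12))
  expect_true(all(sc$table$p_a_bonf <= 1))

  expect_error(lagged_varpart(Y[1:10, ], X1[1:10, ], X2[1:10, , drop = FALSE]),
               class = "bloomkit_window_error")
})

test_that("a response driven at a known lag is localized by the scan", {
  set.seed(85)
  n <- 40
  x2 <- rlnorm(n, log(40), 0.3) + rbinom(n, 1, 0.2) * runif(n, 60, 120)
  y <- 0.02 * c(rep(0, 3), pmax(0, x2[1:(n - 3)] - 80)) + rnorm(n, 0, 0.1)
  Y <- cbind(y1 = y, y2 = y + rnorm(n, 0, 0.1), y3 = y + rnorm(n, 0, 0.1))
  X1 <- matrix(rnorm(2 * n), n)
  sc <- lagged_varpart(Y, X1, cbind(pm = x2), lags = 0:7, n_perm = 99, seed = 3)
  expect_equal(sc$table$lag[which.max(sc$table$c_adj)], 3)
})

test_that("all-subsets OLS finds injected drivers and refuses collinearity", {
  set.seed(90)
  n <- 60
  X <- data.frame(temp = rnorm(n), pico = rnorm(n), sal = rnorm(n), sec = rnorm(n))
  y <- 1.2 * X$temp + 0.9 * X$pico + rnorm(n, 0, 0.8)
  fit <- intrinsic_driver_regression(y, X)
  expect_equal(nrow(fit$table), 16)
  expect_true(all(c("temp", "pico") %in% fit$best_predictors))

  hit <- sum(vapply(1:20, function(s) {
    set.seed(400 + s)
    X <- data.frame(temp = rnorm(n), pico = rnorm(n), sal = rnorm(n))
    y <- 1.2 * X$temp + 0.9 * X$pico + rnorm(n, 0, 0.8)
    f <- intrinsic_driver_regression(y, X)
    all(c("temp", "pico") %in% f$best_predictors)
  }, logical(1)))
  expect_gte(hit, 18)

  Xc <- cbind(X, dup = X$temp * 2)
  expect_error(intrinsic_driver_regression(y, Xc),
               class = "bloomkit_collinearity_error")
})
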