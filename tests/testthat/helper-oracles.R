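## Independent oracles used across the suite. Each is a deliberately naive
## re-implementation (brute force / nested lm fits), kept separate from the
## package's own code paths.

## direct re-application of the bloom rule, sample by sample
brute_onsets <- function(B, factor = 3, abs_threshold = 4, ci_level = 0.9,
                         mode = "either") {
  ci_thr <- if (mode %in% c("ci", "either", "both"))
    mean(B) + qnorm((1 + ci_level) / 2) * sd(B) / sqrt(length(B)) else NA
  out <- rep(NA_integer_, length(B))
  for (i in 2:length(B)) {
    grew <- if (B[i - 1] == 0) B[i] > 0 else B[i] / B[i - 1] > factor
    of <- B[i] > abs_threshold
    oc <- !is.na(ci_thr) && B[i] > ci_thr
    over <- switch(mode, fixed = of, ci = oc, either = of || oc, both = of && oc)
    out[i] <- as.integer(grew && over)
  }
  out
}

## exhaustive minimum-RSS segmentation: enumerate every breakpoint placement
exhaustive_segmentation <- function(y, K, min_seg_len = 2L) {
  n <- length(y)
  rss <- function(seg) sum((seg - mean(seg))^2)
  if (K == 1L) return(list(breakpoints = integer(0), J = rss(y)))
  best <- list(J = Inf)
  combos <- combn(n - 1L, K - 1L)
  for (c_i in seq_len(ncol(combos))) {
    bp <- combos[, c_i]
    bounds <- c(0L, bp, n)
    if (any(diff(bounds) < min_seg_len)) next
    J <- sum(vapply(seq_len(K), function(s)
      rss(y[(bounds[s] + 1L):bounds[s + 1L]]), numeric(1)))
    if (J < best$J - 1e-12) best <- list(breakpoints = bp, J = J)
  }
  best
}

## nested-model R2 route: multivariate R2 of Y on X via per-column lm fits
lm_r2 <- function(Y, X) {
  Y <- as.matrix(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  if (is.null(X) || NCOL(X) == 0) return(0)
  X <- as.matrix(X)
  ess <- sum(vapply(seq_len(ncol(Yc)), function(j) {
    f <- lm(Yc[, j] ~ X)
    sum((fitted(f) - mean(Yc[, j]))^2)
  }, numeric(1)))
  ess / sum(Yc^2)
}

## small deterministic plankton table for I/O and demography tests
toy_series <- function(n = 10, N = 100 * 2^(seq_len(n) - 1)) {
  df <- data.frame(
    lake_id = 1L, week = seq_len(n), day = (seq_len(n) - 1L) * 7L,
    temp_c = 25, salinity = 20, secchi_m = 0.4, pm_mg_l = 40,
    chla_ug_l = 150, species_density_B_dimidiatus = N,
    species_biomass_B_dimidiatus = N * 0.08e-3,
    eggs_B_dimidiatus = 0.5 * N, females_B_dimidiatus = N,
    total_biomass = N * 0.08e-3)
  class(df) <- c("plankton_ts", "data.frame")
  df
}

## noise-free generator configuration: every stochastic amplitude at zero,
## synchronized hatching, deterministic pulse size
noisefree_config <- function(..., seed = 1L) {
  sim_config(temp_sd = 0, salinity_step_sd = 0, chla_sdlog = 0, pm_sdlog = 0,
             egg_sdlog = 0, egg_coupling = 0, d_sd = 0, phyto_sdlog = 0,
             grazing_coeff = 0, lag_offsets = c(0, 0, 0),
             pm_pulse_range = c(200, 200), seed = seed, ...)
}
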