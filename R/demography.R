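#' Instantaneous population growth rate between two censuses
#'
#' Computes the in situ exponential growth rate
#' \eqn{r = (\ln N_2 - \ln N_1)/(t_2 - t_1)} from two density observations.
#' Both densities must be strictly positive: a zero density makes the rate
#' undefined, and callers (see [demographic_series()]) are expected to break
#' the rate chain at such samples rather than interpolate.
#'
#' @param N1,N2 population densities (individuals per litre) at `t1` and `t2`.
#' @param t1,t2 observation times in days; `t2 > t1`.
#' @return Growth rate in d^-1 (vectorised over its arguments).
#' @examples
#' growth_rate(100, 200, 0, 7)  # ln(2)/7
#' @export
growth_rate <- function(N1, N2, t1, t2) {
  if (any(!is.finite(N1)) || any(!is.finite(N2)) || any(N1 <= 0) || any(N2 <= 0))
    stop_bloomkit("densities must be positive and finite; a zero density leaves r undefined",
                  "bloomkit_rate_error")
  if (any(t2 <= t1))
    stop_bloomkit("`t2` must be strictly greater than `t1`", "bloomkit_interval_error")
  (log(N2) - log(N1)) / (t2 - t1)
}

#' Temperature-dependent egg development time
#'
#' Egg development time \eqn{D_E(T)} in days, modelled as an anchored Q10
#' curve \eqn{D_E(T) = D_{ref} \cdot Q_{10}^{(T_{ref} - T)/10}}: development is
#' strictly faster when warmer, the only constraint the egg-ratio method
#' itself imposes. All constants are configurable and any user-supplied
#' monotone function can be passed downstream instead (see
#' [demographic_series()]'s `D_E_fun` argument).
#'
#' @param temperature water temperature in degrees C.
#' @param D_ref reference development time (days) at `T_ref`; default 1 d.
#' @param T_ref reference temperature, default 25 C.
#' @param Q10 factor by which development speeds up per 10 C warming; default 2.5.
#' @param valid_range admissible temperature range; values outside error out.
#' @return Development time in days (vectorised over `temperature`).
#' @export
egg_development_time <- function(temperature, D_ref = 1.0, T_ref = 25, Q10 = 2.5,
                                 valid_range = c(10, 35)) {
  assert_number(D_ref, "D_ref", lower = .Machine$double.eps)
  assert_number(Q10, "Q10", lower = .Machine$double.eps)
  if (any(!is.finite(temperature)) || any(temperature < valid_range[1]) ||
      any(temperature > valid_range[2]))
    stop_bloomkit(sprintf("temperature outside valid range [%g, %g]",
                          valid_range[1], valid_range[2]),
                  "bloomkit_domain_error")
  D_ref * Q10^((T_ref - temperature) / 10)
}

#' Egg-ratio birth rate
#'
#' Per-capita birth rate from the egg-ratio method,
#' \eqn{b = \ln(1 + c_E N_E / (D_E N_\female))}: attached eggs per female,
#' divided by the development time, give the daily per-capita hatch flux of
#' pelagic (amictic) eggs. `b` is non-negative by construction. The
#' multiplicative correction factor `c_E` accommodates corrected egg ratios
#' (e.g. for eggs detached during sampling); it defaults to 1.
#'
#' @param N_E density of eggs attached to females (eggs per litre).
#' @param N_female female density (individuals per litre); must be positive —
#'   a zero female count leaves the ratio undefined and raises an error rather
#'   than silently returning 0.
#' @param D_E egg development time in days (see [egg_development_time()]).
#' @param c_E multiplicative egg-ratio correction factor, default 1.
#' @return Birth rate in d^-1 (vectorised).
#' @examples
#' birth_rate(100, 100, D_E = 1)  # ln(2)
#' @export
birth_rate <- function(N_E, N_female, D_E, c_E = 1.0) {
  if (any(!is.finite(N_E)) || any(N_E < 0))
    stop_bloomkit("`N_E` must be non-negative", "bloomkit_rate_error")
  if (any(!is.finite(N_female)) || any(N_female <= 0))
    stop_bloomkit("`N_female` must be positive; b is undefined at zero females",
                  "bloomkit_rate_error")
  assert_number(D_E, "D_E", lower = .Machine$double.eps)
  assert_number(c_E, "c_E", lower = .Machine$double.eps)
  log(1 + c_E * N_E / (D_E * N_female))
}

#' Death rate as the birth-growth deficit
#'
#' \eqn{d = b - r}. Negative values are permitted and meaningful: they flag
#' population growth that pelagic reproduction cannot account for, the
#' classical field signature of external recruitment from the sediment
#' resting-egg bank. The attached `recruitment_flag` marks those intervals.
#'
#' @param b birth rate (d^-1), see [birth_rate()].
#' @param r growth rate (d^-1), see [growth_rate()].
#' @return Death rate in d^-1 with attribute `recruitment_flag` (logical,
#'   `TRUE` where `d < 0`).
#' @export
death_rate <- function(b, r) {
  if (any(!is.finite(b)) || any(!is.finite(r)))
    stop_bloomkit("`b` and `r` must be finite", "bloomkit_rate_error")
  d <- b - r
  attr(d, "recruitment_flag") <- d < 0
  d
}

#' Death rate implied by a mean lifespan
#'
#' Under exponential survivorship a mean lifespan of `L` days implies a
#' constant mortality hazard of `1/L` per day. The returned value carries a
#' two-decimal presentation string (attribute `"presented"`), matching how
#' such literature-derived rates are usually quoted (e.g. a 9.5 d lifespan is
#' quoted as 0.11 d^-1).
#'
#' @param mean_lifespan mean lifespan in days, > 0.
#' @return Death rate in d^-1; attribute `presented` holds the value rounded
#'   to two decimals as a string.
#' @examples
#' lifespan_death_rate(9.5)
#' @export
lifespan_death_rate <- function(mean_lifespan) {
  if (!is.numeric(mean_lifespan) || any(!is.finite(mean_lifespan)) ||
      any(mean_lifespan <= 0))
    stop_bloomkit("`mean_lifespan` must be positive", "bloomkit_domain_error")
  d <- 1 / mean_lifespan
  attr(d, "presented") <- sprintf("%.2f", d)
  d
}

#' Interval-by-interval demographic series for one species
#'
#' Assembles the egg-ratio demography over consecutive sampling occasions of a
#' plankton time series: for each interval it reports the growth rate `r`
#' from the density pair, the birth rate `b` from the egg and female densities
#' at the interval start, the death rate `d = b - r`, the egg ratio `E`, and
#' the development time `D_E` at the start temperature. Intervals touching a
#' zero density are emitted with `r` and `d` missing (the rate chain is broken,
#' never interpolated); `b` is still reported where females are present.
#'
#' @param series a `plankton_ts` data frame (see [read_timeseries_csv()] or
#'   [simulate_lakes()]) with columns `day`, `species_density_<species>`,
#'   `eggs_<species>`, `females_<species>` and `temp_c`.
#' @param species species name matching the column suffix.
#' @param c_E egg-ratio correction factor passed to [birth_rate()].
#' @param D_E_fun function mapping temperature to development time (days);
#'   defaults to [egg_development_time()].
#' @return A data frame of class `demographic_series`, one row per consecutive
#'   sample pair, with columns `interval`, `t1`, `t2`, `N1`, `N2`, `E`, `D_E`,
#'   `r`, `b`, `d`, `recruitment_flag`.
#' @export
demographic_series <- function(series, species, c_E = 1.0,
                               D_E_fun = egg_development_time) {
  dens_col <- paste0("species_density_", species)
  egg_col  <- paste0("eggs_", species)
  fem_col  <- paste0("females_", species)
  for (cl in c(dens_col, egg_col, fem_col, "day", "temp_c"))
    if (!cl %in% names(series))
      stop_bloomkit(sprintf("column `%s` missing from series", cl),
                    "bloomkit_data_error")
  n <- nrow(series)
  if (n < 2L || sum(series[[dens_col]] > 0, na.rm = TRUE) < 2L)
    stop_bloomkit("need at least two samples with positive densities",
                  "bloomkit_insufficient_data")
  i1 <- seq_len(n - 1L); i2 <- i1 + 1L
  N1 <- series[[dens_col]][i1]; N2 <- series[[dens_col]][i2]
  t1 <- series$day[i1];         t2 <- series$day[i2]
  NE <- series[[egg_col]][i1];  NF <- series[[fem_col]][i1]
  D_E <- D_E_fun(series$temp_c[i1])
  E <- ifelse(NF > 0, NE / NF, NA_real_)
  b <- ifelse(NF > 0, log(1 + c_E * NE / (D_E * NF)), NA_real_)
  ok <- is.finite(N1) & is.finite(N2) & N1 > 0 & N2 > 0
  r <- rep(NA_real_, n - 1L)
  r[ok] <- (log(N2[ok]) - log(N1[ok])) / (t2[ok] - t1[ok])
  d <- b - r
  out <- data.frame(interval = i1, t1 = t1, t2 = t2, N1 = N1, N2 = N2,
                    E = E, D_E = D_E, r = r, b = b, d = d,
                    recruitment_flag = !is.na(d) & d < 0)
  class(out) <- c("demographic_series", "data.frame")
  attr(out, "species") <- species
  out
}

#' @export
print.demographic_series <- function(x, ...) {
  cat("Egg-ratio demographic series:", attr(x, "species") %||% "?", "\n")
  cat(sprintf("%d intervals; mean b = %.3f, mean d = %.3f d^-1; %d recruitment-flagged\n",
              nrow(x), mean(x$b, na.rm = TRUE), mean(x$d, na.rm = TRUE),
              sum(x$recruitment_flag, na.rm = TRUE)))
  print.data.frame(utils::head(as.data.frame(x), 8), digits = 3)
  if (nrow(x) > 8) cat("...", nrow(x) - 8, "more intervals\n")
  invisible(x)
}
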