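#' Scenario configuration for population projection
#'
#' @param N0 starting density (individuals per litre), > 0.
#' @param d scenario death rate (d^-1). May be negative: a negative `d` mimics
#'   net recruitment of resting eggs from the sediment egg bank. The canonical
#'   scenario set is `c(0, 0.11, 0.43)`: maximal intrinsic growth, age-related
#'   losses only, and the field-mean mortality.
#' @param horizon projection horizon in days, > 0.
#' @param step projection step in days (default 1).
#' @param reps bootstrap replicates for [bootstrap_trajectory()] (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return Validated list of class `scenario_config`.
#' @export
scenario_config <- function(N0, d, horizon, step = 1, reps = 1000L, seed = 1L) {
  assert_number(N0, "N0", lower = .Machine$double.eps)
  assert_number(d, "d")
  assert_number(horizon, "horizon", lower = .Machine$double.eps)
  assert_number(step, "step", lower = .Machine$double.eps)
  reps <- assert_count(reps, "reps", min = 1L)
  structure(list(N0 = N0, d = d, horizon = horizon, step = step,
                 reps = reps, seed = seed),
            class = "scenario_config")
}

## expand a per-day birth-rate series onto the projection grid
.b_on_grid <- function(b_series, times) {
  # piecewise-constant: b during (t, t+1] is the last observed daily value
  idx <- pmin(floor(times[-length(times)]) + 1L, length(b_series))
  b_series[idx]
}

#' Deterministic birth-death population projection
#'
#' Projects `N(t + step) = N(t) * exp(step * (b(t) - d))` from `N0` over the
#' horizon, holding the birth rate piecewise-constant within each day (weekly
#' egg data are carried forward to daily projection steps by the caller).
#'
#' @param scenario a [scenario_config()].
#' @param b_series daily birth rates (d^-1); element `i` applies during day
#'   `i`. Must cover the horizon.
#' @return Data frame of class `trajectory` with columns `time` (days) and `N`.
#' @examples
#' sc <- scenario_config(N0 = 100, d = 0, horizon = 7)
#' project_population(sc, rep(log(2), 7))  # doubles daily: 100 * 2^7
#' @export
project_population <- function(scenario, b_series) {
  if (!inherits(scenario, "scenario_config"))
    stop_bloomkit("`scenario` must be a scenario_config", "bloomkit_config_error")
  if (length(b_series) < ceiling(scenario$horizon))
    stop_bloomkit(sprintf("b_series (%d daily values) does not cover the %g-day horizon",
                          length(b_series), scenario$horizon),
                  "bloomkit_coverage_error")
  times <- seq(0, scenario$horizon, by = scenario$step)
  if (times[length(times)] < scenario$horizon)
    times <- c(times, scenario$horizon)
  b_step <- .b_on_grid(b_series, times)
  dt <- diff(times)
  logN <- log(scenario$N0) + cumsum(dt * (b_step - scenario$d))
  out <- data.frame(time = times, N = c(scenario$N0, exp(logN)))
  class(out) <- c("trajectory", "data.frame")
  attr(out, "d") <- scenario$d
  out
}

#' Bootstrap confidence envelope for a projected population
#'
#' Propagates egg-counting uncertainty into the projection: per replicate the
#' egg and female counts at each sampling date are resampled as Poisson draws
#' around the observed counts, the birth-rate series is recomputed via
#' [birth_rate()], held piecewise-constant between sampling dates, and the
#' population is projected with [project_population()]. Envelopes are the
#' pointwise 2.5/97.5 percentiles across replicates. Female draws of zero are
#' floored at one so the egg ratio stays defined (a vanishing female count in
#' a resample is a counting artefact, not a population state).
#'
#' @param egg_data data frame with columns `day`, `eggs`, `females` (counts in
#'   the counted subsample; only their ratio enters the birth rate) and
#'   `temperature` (deg C).
#' @param scenario a [scenario_config()]; `reps >= 100` recommended for CIs.
#' @param c_E egg-ratio correction factor.
#' @param D_E_fun temperature-to-development-time function.
#' @return Object of class `trajectory_ensemble`: list with `times`, `median`,
#'   `lower95`, `upper95`, `d`, `reps`.
#' @export
bootstrap_trajectory <- function(egg_data, scenario, c_E = 1.0,
                                 D_E_fun = egg_development_time) {
  if (!inherits(scenario, "scenario_config"))
    stop_bloomkit("`scenario` must be a scenario_config", "bloomkit_config_error")
  if (scenario$reps < 2L)
    stop_bloomkit("at least 2 bootstrap replicates are required for an envelope",
                  "bloomkit_config_error")
  for (cl in c("day", "eggs", "females", "temperature"))
    if (!cl %in% names(egg_data))
      stop_bloomkit(sprintf("`egg_data` lacks column `%s`", cl), "bloomkit_data_error")
  egg_data$day <- egg_data$day - min(egg_data$day)

  D_E <- D_E_fun(egg_data$temperature)
  days <- seq_len(ceiling(scenario$horizon))
  # which sampling occasion governs each projection day (carry forward)
  occ <- findInterval(days - 1L, egg_data$day)
  occ[occ < 1L] <- 1L

  set.seed(scenario$seed)
  n_t <- length(seq(0, scenario$horizon, by = scenario$step))
  traj <- matrix(NA_real_, scenario$reps, n_t)
  for (rep in seq_len(scenario$reps)) {
    eggs_r <- stats::rpois(nrow(egg_data), egg_data$eggs)
    fem_r <- pmax(1L, stats::rpois(nrow(egg_data), egg_data$females))
    b_occ <- birth_rate(eggs_r, fem_r, D_E, c_E)
    tr <- project_population(scenario, b_occ[occ])
    traj[rep, ] <- tr$N
  }
  times <- project_population(scenario, rep(0, length(days)))$time
  q <- apply(traj, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  out <- list(times = times, median = q[2, ], lower95 = q[1, ], upper95 = q[3, ],
              d = scenario$d, reps = scenario$reps, N0 = scenario$N0)
  class(out) <- "trajectory_ensemble"
  out
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  k <- length(x$times)
  cat(sprintf("Projected population ensemble (d = %.2f d^-1, %d replicates)\n",
              x$d, x$reps))
  cat(sprintf("  day %g: median %.3g [%.3g, %.3g] ind/L\n",
              x$times[k], x$median[k], x$lower95[k], x$upper95[k]))
  invisible(x)
}

#' @export
plot.trajectory_ensemble <- function(x, ..., log = "y",
                                     xlab = "Time (d)", ylab = "Density (ind/L)") {
  graphics::plot(x$times, x$median, type = "n", log = log,
                 ylim = range(c(x$lower95, x$upper95)), xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(x$times, rev(x$times)), c(x$lower95, rev(x$upper95)),
                    col = "#9ecae180", border = NA)
  graphics::lines(x$times, x$median, lwd = 2)
  invisible(x)
}

#' External (resting-egg) recruitment from the observed-minus-modelled deficit
#'
#' A conservative estimate of benthic recruitment: the observed density minus
#' the upper 95% envelope of the pelagic-reproduction-only projection, floored
#' at zero. The estimate deliberately conflates hatchlings with the offspring
#' they produced before the observation — the field data cannot separate them.
#'
#' @param observed observed density (ind/L) at time `at`, > 0.
#' @param ensemble a `trajectory_ensemble`, or a single numeric upper bound.
#' @param at observation time in days (default: the ensemble's last time).
#' @return Object of class `recruitment_estimate`: list with `observed`,
#'   `modelled_upper`, `external` (ind/L) and `fraction` of the observed
#'   population attributed to external recruitment.
#' @examples
#' external_recruitment(1.65e5, 5.5e4)  # two thirds external
#' @export
external_recruitment <- function(observed, ensemble, at = NULL) {
  assert_number(observed, "observed", lower = .Machine$double.eps)
  if (is.numeric(ensemble)) {
    upper <- ensemble
  } else {
    if (!inherits(ensemble, "trajectory_ensemble"))
      stop_bloomkit("`ensemble` must be a trajectory_ensemble or a numeric bound",
                    "bloomkit_config_error")
    at <- at %||% max(ensemble$times)
    if (at < min(ensemble$times) || at > max(ensemble$times))
      stop_bloomkit("observation time outside the projected horizon",
                    "bloomkit_coverage_error")
    upper <- stats::approx(ensemble$times, ensemble$upper95, xout = at)$y
  }
  external <- max(0, observed - upper)
  out <- list(observed = observed, modelled_upper = upper,
              external = external, fraction = external / observed)
  class(out) <- "recruitment_estimate"
  out
}

#' @export
print.recruitment_estimate <- function(x, ...) {
  cat("External-recruitment estimate (conservative, upper-95% based)\n")
  cat(sprintf("  observed %.3g ind/L, modelled upper bound %.3g ind/L\n",
              x$observed, x$modelled_upper))
  cat(sprintf("  external %.3g ind/L = %.1f%% of the observed population\n",
              x$external, 100 * x$fraction))
  invisible(x)
}
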