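#' Bloom-onset rule
#'
#' A sampling occasion is a bloom onset when total rotifer biomass (1) jumped
#' by more than `factor` relative to the previous sample and (2) exceeds an
#' absolute threshold and/or a lake-specific confidence bound, per `mode`:
#' \describe{
#'   \item{`"fixed"`}{biomass > `abs_threshold` (default 4 g DM m^-3)}
#'   \item{`"ci"`}{biomass > the lake-specific upper CI bound of mean biomass}
#'   \item{`"either"`}{either bound exceeded (default)}
#'   \item{`"both"`}{both bounds exceeded}
#' }
#' The default growth factor 3.0 is the literal "> 200% increase"; set
#' `factor = 2` for a plain doubling rule.
#'
#' @param factor multiplicative growth threshold (> 1).
#' @param abs_threshold absolute biomass threshold (g DM m^-3).
#' @param ci_level confidence level of the lake-specific bound.
#' @param mode threshold combination mode.
#' @return List of class `bloom_rule`.
#' @export
bloom_rule <- function(factor = 3.0, abs_threshold = 4.0, ci_level = 0.90,
                       mode = c("either", "fixed", "ci", "both")) {
  mode <- match.arg(mode)
  if (!is.numeric(factor) || factor <= 1)
    stop_bloomkit("`factor` must exceed 1", "bloomkit_config_error")
  assert_number(abs_threshold, "abs_threshold", lower = .Machine$double.eps)
  if (ci_level <= 0 || ci_level >= 1)
    stop_bloomkit("`ci_level` must lie in (0, 1)", "bloomkit_config_error")
  structure(list(factor = factor, abs_threshold = abs_threshold,
                 ci_level = ci_level, mode = mode), class = "bloom_rule")
}

#' Lake-specific upper confidence bound of mean biomass
#'
#' Normal-theory upper limit `mean + z * sd / sqrt(n)` at the given two-sided
#' level (z = 1.6449 at level 0.90), on the untransformed biomass scale.
#' Accounts for productivity differences among lakes when flagging blooms.
#'
#' @param biomass numeric biomass series (g DM m^-3); >= 3 non-missing values.
#' @param level two-sided confidence level, default 0.90.
#' @return Upper bound in g DM m^-3.
#' @export
lake_ci_threshold <- function(biomass, level = 0.90) {
  x <- biomass[!is.na(biomass)]
  if (length(x) < 3L)
    stop_bloomkit("need >= 3 non-missing biomass values for a lake CI",
                  "bloomkit_insufficient_data")
  if (level <= 0 || level >= 1)
    stop_bloomkit("`level` must lie in (0, 1)", "bloomkit_config_error")
  mean(x) + stats::qnorm((1 + level) / 2) * stats::sd(x) / sqrt(length(x))
}

#' Detect bloom onsets in a plankton time series
#'
#' Applies a [bloom_rule()] to the total rotifer biomass of one lake. A
#' predecessor biomass of exactly zero with the current sample above threshold
#' counts as an onset (appearance from zero is the strongest possible
#' increase). Returns the binomial onset vector (first sample is `NA`: it has
#' no predecessor) plus one event record per onset, with the magnitude class
#' used in multi-lake bloom maps (4-8, 8-20, >= 20 g DM m^-3).
#'
#' @param series a `plankton_ts` data frame, or any data frame with a
#'   `total_biomass` column (overridable via `column`).
#' @param rule a [bloom_rule()].
#' @param column name of the biomass column.
#' @return List of class `bloom_events`: `onset` (0/1/NA per sample),
#'   `events` (data frame: `lake_id`, `index`, `biomass`, `class`),
#'   `ci_threshold` (the lake bound, if used).
#' @export
detect_bloom_onsets <- function(series, rule = bloom_rule(),
                                column = "total_biomass") {
  if (!column %in% names(series))
    stop_bloomkit(sprintf("biomass column `%s` missing", column),
                  "bloomkit_data_error")
  B <- series[[column]]
  if (length(B) < 2L)
    stop_bloomkit("need >= 2 samples to detect onsets", "bloomkit_insufficient_data")
  if (anyNA(B))
    stop_bloomkit("missing biomass values in series", "bloomkit_data_error")
  ci_thr <- if (rule$mode %in% c("ci", "either", "both"))
    lake_ci_threshold(B, rule$ci_level) else NA_real_

  n <- length(B)
  onset <- rep(NA_integer_, n)
  for (i in 2:n) {
    grew <- if (B[i - 1] == 0) B[i] > 0 else B[i] / B[i - 1] > rule$factor
    over_fixed <- B[i] > rule$abs_threshold
    over_ci <- !is.na(ci_thr) && B[i] > ci_thr
    over <- switch(rule$mode,
                   fixed = over_fixed,
                   ci = over_ci,
                   either = over_fixed || over_ci,
                   both = over_fixed && over_ci)
    onset[i] <- as.integer(grew && over)
  }
  idx <- which(onset == 1L)
  events <- data.frame(
    lake_id = if ("lake_id" %in% names(series)) series$lake_id[idx]
              else rep(NA_integer_, length(idx)),
    index = idx, biomass = B[idx],
    class = cut(B[idx], c(-Inf, 8, 20, Inf), labels = c("4-8", "8-20", ">=20")))
  structure(list(onset = onset, events = events, ci_threshold = ci_thr,
                 rule = rule), class = "bloom_events")
}

#' @export
print.bloom_events <- function(x, ...) {
  cat(sprintf("Bloom onsets: %d of %d usable samples (rule: factor %.1f, mode '%s')\n",
              nrow(x$events), sum(!is.na(x$onset)), x$rule$factor, x$rule$mode))
  if (nrow(x$events)) print.data.frame(x$events, digits = 3)
  invisible(x)
}

#' Standardize covariates across a multi-lake dataset
#'
#' Pooled (across-lake) Z-standardization of the named variables, as used
#' before regression analysis; a range-transform mode (min to 0, max to 1) is
#' provided for cross-lake plotting.
#'
#' @param dataset stacked data frame (e.g. [as_meta_df()] output).
#' @param variables column names to transform.
#' @param mode `"z"` (default) or `"range"`.
#' @return The data frame with the named columns transformed.
#' @export
standardize_covariates <- function(dataset, variables, mode = c("z", "range")) {
  mode <- match.arg(mode)
  for (v in variables) {
    if (!v %in% names(dataset))
      stop_bloomkit(sprintf("variable `%s` not present", v), "bloomkit_data_error")
    x <- dataset[[v]]
    if (mode == "z") {
      s <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0)
        stop_bloomkit(sprintf("variable `%s` has zero pooled variance", v),
                      "bloomkit_degenerate_variable")
      dataset[[v]] <- (x - mean(x, na.rm = TRUE)) / s
    } else {
      r <- range(x, na.rm = TRUE)
      if (r[2] == r[1])
        stop_bloomkit(sprintf("variable `%s` has zero range", v),
                      "bloomkit_degenerate_variable")
      dataset[[v]] <- (x - r[1]) / (r[2] - r[1])
    }
  }
  dataset
}

#' Mixed-effect logistic bloom-probability model
#'
#' Fits bloom-onset probability against fixed-effect predictors with a lake
#' random intercept, maximizing the marginal likelihood by adaptive
#' Gauss-Hermite quadrature (order 20; a single scalar random effect keeps the
#' integral one-dimensional and the fit deterministic). With `random = FALSE`
#' (or when the data hold a single lake) an ordinary logistic regression is
#' fitted instead — the nested model with the random-intercept variance pinned
#' at zero. Complete separation or other non-convergence is reported in the
#' returned object, never raised as an error.
#'
#' @param dataset stacked data frame with an outcome column, predictor columns
#'   and a `lake_id` column.
#' @param fixed character vector of fixed-effect predictor names.
#' @param outcome name of the binary (0/1) outcome column; `NA` rows dropped.
#' @param random include the lake random intercept (default `TRUE`).
#' @param nAGQ quadrature order for the marginal likelihood.
#' @return Object of class `bloom_logit`: coefficient table (`estimate`,
#'   `se`, `z`, `p`), `ranef_var`, `logLik`, `AIC`, `n`, `converged`,
#'   `diagnostic`, and the underlying fit.
#' @export
fit_bloom_logit <- function(dataset, fixed, outcome = "onset",
                            random = TRUE, nAGQ = 20L) {
  for (v in c(fixed, outcome))
    if (!v %in% names(dataset))
      stop_bloomkit(sprintf("column `%s` not present", v), "bloomkit_data_error")
  keep <- stats::complete.cases(dataset[, c(fixed, outcome), drop = FALSE])
  dat <- dataset[keep, , drop = FALSE]
  y <- dat[[outcome]]
  if (!all(y %in% c(0, 1)))
    stop_bloomkit("outcome must be binary 0/1", "bloomkit_data_error")
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  use_re <- random && "lake_id" %in% names(dat) &&
    length(unique(dat$lake_id)) >= 2L

  diagnostic <- character(0)
  converged <- TRUE
  if (use_re) {
    fml <- stats::as.formula(paste(outcome, "~", rhs, "+ (1 | lake_id)"))
    fit <- withCallingHandlers(
      tryCatch(lme4::glmer(fml, data = dat, family = stats::binomial(), nAGQ = nAGQ),
               error = function(e) e),
      warning = function(w) {
        diagnostic <<- c(diagnostic, conditionMessage(w))
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    if (inherits(fit, "error"))
      return(structure(list(coefficients = NULL, ranef_var = NA_real_,
                            logLik = NA_real_, AIC = NA_real_, n = nrow(dat),
                            converged = FALSE, diagnostic = conditionMessage(fit),
                            fixed = fixed, fit = NULL),
                       class = "bloom_logit"))
    sm <- summary(fit)$coefficients
    ranef_var <- as.numeric(lme4::VarCorr(fit)$lake_id[1])
    ll <- as.numeric(stats::logLik(fit))
    aic <- stats::AIC(fit)
  } else {
    fml <- stats::as.formula(paste(outcome, "~", rhs))
    fit <- withCallingHandlers(
      stats::glm(fml, data = dat, family = stats::binomial()),
      warning = function(w) {
        diagnostic <<- c(diagnostic, conditionMessage(w))
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    sm <- summary(fit)$coefficients
    ranef_var <- 0
    ll <- as.numeric(stats::logLik(fit))
    aic <- stats::AIC(fit)
  }
  if (any(!is.finite(sm)) || any(sm[, 2] > 50)) {
    # diverging coefficients / standard errors: the usual face of complete
    # separation in logistic fits
    converged <- FALSE
    diagnostic <- c(diagnostic,
                    "standard errors diverged; possible complete separation")
  }
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = sm[, 4], row.names = NULL)
  structure(list(coefficients = coefs, ranef_var = ranef_var, logLik = ll,
                 AIC = aic, n = nrow(dat), converged = converged,
                 diagnostic = paste(diagnostic, collapse = "; "),
                 fixed = fixed, fit = fit),
            class = "bloom_logit")
}

#' @export
print.bloom_logit <- function(x, ...) {
  cat("Bloom-probability logistic model",
      if (x$ranef_var > 0) "(lake random intercept)" else "(no random effect)", "\n")
  if (is.null(x$coefficients)) {
    cat("  fit failed:", x$diagnostic, "\n")
    return(invisible(x))
  }
  print.data.frame(x$coefficients, digits = 3, row.names = FALSE)
  cat(sprintf("  random-intercept var %.3f | logLik %.2f | AIC %.2f | n = %d%s\n",
              x$ranef_var, x$logLik, x$AIC, x$n,
              if (!x$converged) " | NOT CONVERGED" else ""))
  invisible(x)
}

#' @export
coef.bloom_logit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' All-subsets AIC selection for the bloom-probability model
#'
#' Fits every subset of the candidate predictors (including the
#' intercept-only model) with [fit_bloom_logit()] and returns the
#' minimum-AIC fit together with the full AIC table. Subsets whose fit fails
#' are recorded and excluded from the ranking with a warning.
#'
#' @param dataset stacked data frame (see [fit_bloom_logit()]).
#' @param candidates candidate predictor names (at most 12: `2^k` fits).
#' @param outcome binary outcome column.
#' @param ... passed to [fit_bloom_logit()] (e.g. `random = FALSE`).
#' @return Object of class `bloom_aic`: `best` (a `bloom_logit`), `table`
#'   (one row per subset: predictors, k, AIC, delta), `fits` (optional).
#' @export
select_model_aic <- function(dataset, candidates, outcome = "onset", ...) {
  k <- length(candidates)
  if (k > 12L)
    stop_bloomkit("at most 12 candidate predictors (2^k enumeration)",
                  "bloomkit_config_error")
  subsets <- lapply(0:(2^k - 1), function(m) candidates[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
  rows <- vector("list", length(subsets))
  fits <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    f <- tryCatch(fit_bloom_logit(dataset, subsets[[i]], outcome = outcome, ...),
                  error = function(e) e)
    failed <- inherits(f, "error") || is.null(f$coefficients)
    if (failed)
      warning(sprintf("subset {%s} failed to fit; excluded from ranking",
                      paste(subsets[[i]], collapse = ", ")), call. = FALSE)
    rows[[i]] <- data.frame(
      predictors = paste(subsets[[i]], collapse = "+"),
      k = length(subsets[[i]]),
      AIC = if (failed) NA_real_ else f$AIC,
      converged = if (failed) FALSE else f$converged)
    fits[[i]] <- if (failed) NULL else f
  }
  tab <- do.call(rbind, rows)
  tab$delta <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  ord <- order(tab$AIC)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(best = fits[ord][[1]], table = tab,
                 best_predictors = subsets[ord][[1]]),
            class = "bloom_aic")
}

#' @export
print.bloom_aic <- function(x, ...) {
  cat("All-subsets AIC selection:", nrow(x$table), "models\n")
  cat("Best subset:", if (length(x$best_predictors))
    paste(x$best_predictors, collapse = " + ") else "(intercept only)", "\n")
  print.data.frame(utils::head(x$table, 6), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Paired pre-bloom vs onset contrast
#'
#' Paired comparison of a variable (typically the relative contribution of
#' filamentous cyanobacteria) between each bloom onset and its immediately
#' preceding sample. If the paired differences have zero variance the t
#' statistic is undefined; the degenerate case is reported with a flag
#' (`p = 0` for a constant nonzero shift, `p = 1` for identical values).
#'
#' @param dataset stacked data frame with the variable of interest.
#' @param events a `bloom_events` object or a data frame with `index` (and
#'   `lake_id` if the dataset holds several lakes).
#' @param variable column name to contrast.
#' @return List of class `prebloom_contrast`: `mean_diff`, `t`, `df`, `p`,
#'   `n_pairs`, `degenerate`.
#' @export
prebloom_contrast <- function(dataset, events, variable) {
  if (!variable %in% names(dataset))
    stop_bloomkit(sprintf("variable `%s` not present", variable), "bloomkit_data_error")
  ev <- if (inherits(events, "bloom_events")) events$events else events
  if (is.null(ev) || nrow(ev) < 2L)
    stop_bloomkit("need >= 2 bloom events with pre-bloom samples",
                  "bloomkit_insufficient_data")
  # indices are within-lake row positions; map to stacked rows when needed
  row_of <- function(lake, idx) {
    if (!"lake_id" %in% names(dataset) || all(is.na(ev$lake_id))) return(idx)
    which(dataset$lake_id == lake)[idx]
  }
  onset_rows <- mapply(row_of, ev$lake_id, ev$index)
  pre_rows <- mapply(row_of, ev$lake_id, ev$index - 1L)
  onset_v <- dataset[[variable]][onset_rows]
  pre_v <- dataset[[variable]][pre_rows]
  diffs <- onset_v - pre_v
  if (stats::sd(diffs) == 0) {
    out <- list(mean_diff = mean(diffs), t = if (mean(diffs) == 0) 0 else Inf,
                df = length(diffs) - 1L,
                p = if (mean(diffs) == 0) 1 else 0,
                n_pairs = length(diffs), degenerate = TRUE)
  } else {
    tt <- stats::t.test(onset_v, pre_v, paired = TRUE)
    out <- list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value,
                n_pairs = length(diffs), degenerate = FALSE)
  }
  class(out) <- "prebloom_contrast"
  out
}

#' @export
print.prebloom_contrast <- function(x, ...) {
  cat(sprintf("Paired pre-bloom vs onset contrast: mean diff %.4g, t = %.3g, df = %d, p = %.3g%s\n",
              x$mean_diff, x$t, x$df, x$p,
              if (x$degenerate) " (degenerate: zero-variance differences)" else ""))
  invisible(x)
}

#' Average bloom frequency
#'
#' Mean interval between blooms: total monitored months divided by the total
#' onset count. Zero events yield an infinite interval, flagged.
#'
#' @param months_monitored per-lake monitored durations in months (summed).
#' @param n_events total number of bloom onsets.
#' @return List of class `bloom_frequency`: `months_per_bloom`,
#'   `blooms_per_month`, `n_events`, `months`, `no_events` flag.
#' @examples
#' bloom_frequency(187.2, 36)  # one bloom every 5.2 months
#' @export
bloom_frequency <- function(months_monitored, n_events) {
  months <- sum(months_monitored)
  assert_number(months, "months_monitored", lower = .Machine$double.eps)
  if (n_events < 0 || n_events != floor(n_events))
    stop_bloomkit("`n_events` must be a non-negative integer", "bloomkit_config_error")
  out <- list(months_per_bloom = if (n_events == 0) Inf else months / n_events,
              blooms_per_month = n_events / months,
              n_events = n_events, months = months, no_events = n_events == 0)
  class(out) <- "bloom_frequency"
  out
}

#' @export
print.bloom_frequency <- function(x, ...) {
  if (x$no_events)
    cat(sprintf("No blooms in %.1f monitored months\n", x$months))
  else
    cat(sprintf("%d blooms in %.1f months: one bloom every %.1f months\n",
                x$n_events, x$months, x$months_per_bloom))
  invisible(x)
}
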