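## ---- matrix helpers ---------------------------------------------------------

.as_matrix <- function(x, name) {
  m <- as.matrix(x)
  if (!is.numeric(m) || anyNA(m))
    stop_bloomkit(sprintf("`%s` must be numeric without missing values", name),
                  "bloomkit_data_error")
  if (is.null(colnames(m))) colnames(m) <- paste0(name, seq_len(ncol(m)))
  m
}

.center <- function(m) sweep(m, 2L, colMeans(m), `-`)

.check_rank <- function(X, name) {
  q <- qr(.center(X))
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop_bloomkit(sprintf("collinear columns in `%s`: %s", name,
                          paste(bad, collapse = ", ")),
                  "bloomkit_collinearity_error")
  }
  invisible(q)
}

## projection of (centred) Y onto the column space of (centred) X
.fit_proj <- function(Yc, Xc) {
  q <- qr(Xc)
  qr.fitted(q, Yc)
}

.r2 <- function(Yc, Xc) {
  if (is.null(Xc) || ncol(Xc) == 0L) return(0)
  Yhat <- .fit_proj(Yc, Xc)
  sum(Yhat^2) / sum(Yc^2)
}

.adj_r2 <- function(r2, n, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)

#' Transform a species matrix before ordination
#'
#' `"standardize"` (default) z-scores each column — appropriate when species
#' biomasses live on very different scales; `"hellinger"` takes the square
#' root of row-relative abundances; `"none"` leaves the matrix untouched.
#'
#' @param Y species matrix (samples x species).
#' @param transform one of `"standardize"`, `"hellinger"`, `"none"`.
#' @return Transformed numeric matrix.
#' @export
transform_species <- function(Y, transform = c("standardize", "hellinger", "none")) {
  transform <- match.arg(transform)
  Y <- .as_matrix(Y, "Y")
  switch(transform,
         standardize = {
           s <- apply(Y, 2L, stats::sd)
           if (any(s == 0))
             stop_bloomkit("zero-variance species column", "bloomkit_degenerate_variable")
           scale(Y)[, , drop = FALSE]
         },
         hellinger = {
           rs <- rowSums(Y)
           if (any(Y < 0) || any(rs <= 0))
             stop_bloomkit("hellinger needs non-negative rows with positive sums",
                           "bloomkit_data_error")
           sqrt(Y / rs)
         },
         none = Y)
}

#' Redundancy analysis (RDA)
#'
#' Constrained ordination of a multivariate response on a predictor matrix:
#' columns of `Y` and `X` are centred, fitted values are the least-squares
#' projection of `Y` onto the span of `X`, and the constrained share of
#' variance is \eqn{R^2 = tr(\hat{Y}^\top \hat{Y}) / tr(Y^\top Y)}, with the
#' Ezekiel adjustment \eqn{1 - (1 - R^2)(n-1)/(n-m-1)}. Canonical axes are the
#' eigenvectors of the fitted cross-product.
#'
#' @param Y response matrix (samples x species), already transformed as
#'   desired (see [transform_species()]).
#' @param X predictor matrix; columns must be linearly independent after
#'   centring (collinearity errors name the offending columns).
#' @return Object of class `rda_fit`: `R2`, `R2_adj`, `n`, `m`, eigenvalues
#'   and canonical axes, fitted values and residuals.
#' @export
rda <- function(Y, X) {
  Y <- .as_matrix(Y, "Y"); X <- .as_matrix(X, "X")
  if (nrow(Y) != nrow(X))
    stop_bloomkit("`Y` and `X` must have matching rows", "bloomkit_data_error")
  .check_rank(X, "X")
  Yc <- .center(Y); Xc <- .center(X)
  Yhat <- .fit_proj(Yc, Xc)
  R2 <- sum(Yhat^2) / sum(Yc^2)
  n <- nrow(Y); m <- ncol(X)
  eig <- eigen(crossprod(Yhat) / (n - 1), symmetric = TRUE)
  structure(list(R2 = R2, R2_adj = .adj_r2(R2, n, m), n = n, m = m,
                 eigenvalues = pmax(eig$values, 0), axes = eig$vectors,
                 fitted = Yhat, residuals = Yc - Yhat),
            class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf("RDA: n = %d, m = %d constraints; R2 = %.4f (adj %.4f)\n",
              x$n, x$m, x$R2, x$R2_adj))
  invisible(x)
}

#' Partial redundancy analysis
#'
#' Conditional (partial) RDA of `Y` on a focal predictor set `X` given a
#' conditioning set `Z`: `Y` and `X` are residualized on `Z` and an RDA is
#' run on the residuals. The conditional \eqn{R^2} equals the nested-model
#' difference \eqn{R^2(X \cup Z) - R^2(Z)} of the total variance of `Y`; the
#' adjusted value is the difference of Ezekiel-adjusted nested \eqn{R^2}
#' (degrees of freedom thereby account for the `Z` columns).
#'
#' @param Y response matrix.
#' @param X focal predictor matrix.
#' @param Z conditioning matrix, or `NULL` for an unconditioned [rda()].
#' @return Object of class `prda_fit`: `R2_cond`, `R2_cond_adj`, `R2_full`
#'   (of `X` and `Z` jointly), `R2_cond_semipartial` (share of the residual
#'   variance after `Z`), `n`, `m`, `q`.
#' @export
partial_rda <- function(Y, X, Z = NULL) {
  if (is.null(Z) || (!is.null(dim(Z)) && ncol(as.matrix(Z)) == 0L)) {
    f <- rda(Y, X)
    return(structure(list(R2_cond = f$R2, R2_cond_adj = f$R2_adj,
                          R2_full = f$R2, R2_cond_semipartial = f$R2,
                          n = f$n, m = f$m, q = 0L), class = "prda_fit"))
  }
  Y <- .as_matrix(Y, "Y"); X <- .as_matrix(X, "X"); Z <- .as_matrix(Z, "Z")
  .check_rank(Z, "Z")
  .check_rank(X, "X")
  # X and Z may overlap in span: the overlap simply ends up in the shared
  # fraction (residualized X columns collapse to zero, conditional R2 -> 0)
  Yc <- .center(Y); Xc <- .center(X); Zc <- .center(Z)
  n <- nrow(Y); m <- ncol(X); q <- ncol(Z)
  # residualization route: project the conditioning set out of both Y and X,
  # then constrain the Y-residuals by the X-residuals; the conditional
  # fraction is expressed against the TOTAL variance of Y (algebraically
  # equal to the nested difference R2(X,Z) - R2(Z), which tests exploit as
  # an independent oracle)
  Yres <- Yc - .fit_proj(Yc, Zc)
  Xres <- Xc - .fit_proj(Xc, Zc)
  # focal columns absorbed by the conditioning set leave nothing to explain;
  # drop them rather than projecting onto numerical noise
  keep <- colSums(Xres^2) > 1e-12 * pmax(colSums(Xc^2), .Machine$double.eps)
  tot <- sum(Yc^2)
  R2_cond <- if (any(keep))
    sum(.fit_proj(Yres, Xres[, keep, drop = FALSE])^2) / tot else 0
  R2_z <- .r2(Yc, Zc)
  R2_full <- R2_z + R2_cond
  adj <- .adj_r2(R2_full, n, m + q) - .adj_r2(R2_z, n, q)
  structure(list(R2_cond = R2_cond, R2_cond_adj = adj, R2_full = R2_full,
                 R2_cond_semipartial = if (R2_z < 1) R2_cond / (1 - R2_z) else 0,
                 n = n, m = m, q = q),
            class = "prda_fit")
}

#' @export
print.prda_fit <- function(x, ...) {
  cat(sprintf("Partial RDA: n = %d, m = %d focal, q = %d conditioning\n",
              x$n, x$m, x$q))
  cat(sprintf("  conditional R2 = %.4f (adj %.4f); joint R2 = %.4f\n",
              x$R2_cond, x$R2_cond_adj, x$R2_full))
  invisible(x)
}

#' Two-set variance partitioning
#'
#' Partitions the variance of `Y` among two predictor sets into the unique
#' fraction of each set (`a`, `c`), the shared fraction (`b`) and the
#' residual; `a + b + c + residual = 1` exactly on the unadjusted scale.
#' Adjusted fractions use nested Ezekiel-adjusted differences and may be
#' slightly negative; they are reported as computed, never truncated.
#'
#' @param Y response matrix (transformed via `transform`).
#' @param X1 first predictor set (e.g. intrinsic growth drivers).
#' @param X2 second predictor set (e.g. particulate matter).
#' @param transform species-matrix transform, see [transform_species()].
#' @return Object of class `varpart_result` with `fractions` (unadjusted) and
#'   `fractions_adj`, each holding `a` (X1 unique), `b` (shared), `c` (X2
#'   unique), `residual`, plus `n` and the set sizes.
#' @export
variance_partition <- function(Y, X1, X2, transform = "standardize") {
  Yt <- transform_species(Y, transform)
  X1 <- .as_matrix(X1, "X1"); X2 <- .as_matrix(X2, "X2")
  n <- nrow(Yt)
  a_fit <- partial_rda(Yt, X1, X2)
  c_fit <- partial_rda(Yt, X2, X1)
  R2_full <- a_fit$R2_full
  a <- a_fit$R2_cond; cc <- c_fit$R2_cond
  b <- R2_full - a - cc
  resid <- 1 - R2_full
  adj_full <- .adj_r2(R2_full, n, ncol(X1) + ncol(X2))
  a_adj <- a_fit$R2_cond_adj; c_adj <- c_fit$R2_cond_adj
  structure(list(
    fractions = c(a = a, b = b, c = cc, residual = resid),
    fractions_adj = c(a = a_adj, b = adj_full - a_adj - c_adj, c = c_adj,
                      residual = 1 - adj_full),
    R2_full = R2_full, R2_full_adj = adj_full,
    n = n, m1 = ncol(X1), m2 = ncol(X2), transform = transform),
    class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat(sprintf("Variance partitioning (n = %d; %d + %d predictors)\n",
              x$n, x$m1, x$m2))
  tab <- rbind(unadjusted = x$fractions, adjusted = x$fractions_adj)
  print(round(tab, 4))
  if (any(x$fractions_adj < 0))
    cat("  note: adjusted fractions can be negative; reported as computed\n")
  invisible(x)
}

#' Permutation test for a (partial) RDA
#'
#' Tests the conditional association of `Y` with `X` given `Z` using the
#' pseudo-F statistic
#' \eqn{F = (R^2_{cond}/m) / ((1 - R^2_{full})/(n - m - q - 1))} and
#' permutation of the residuals of the reduced model: replicate responses are
#' the `Z`-fitted values plus row-permuted `Z`-residuals, which is exact under
#' the null of no conditional association. `p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})`.
#'
#' @param Y response matrix (transform applied beforehand by the caller).
#' @param X focal predictors.
#' @param Z conditioning predictors or `NULL`.
#' @param n_perm number of permutations (>= 99; fewer warns about resolution).
#' @param seed RNG seed.
#' @return List of class `rda_permtest`: `F`, `p`, `n_perm`, `R2_cond`.
#' @export
permutation_test <- function(Y, X, Z = NULL, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L)
    warning("fewer than 99 permutations gives poor p-value resolution", call. = FALSE)
  Y <- .as_matrix(Y, "Y"); X <- .as_matrix(X, "X")
  has_z <- !is.null(Z) && ncol(as.matrix(Z)) > 0L
  if (has_z) Z <- .as_matrix(Z, "Z")
  n <- nrow(Y); m <- ncol(X); q <- if (has_z) ncol(Z) else 0L
  Yc <- .center(Y); Xc <- .center(X)
  Zc <- if (has_z) .center(Z) else NULL
  XZ <- if (has_z) cbind(Zc, Xc) else Xc

  fit_red <- if (has_z) .fit_proj(Yc, Zc) else matrix(0, n, ncol(Yc))
  res_red <- Yc - fit_red
  pseudo_f <- function(Ymat) {
    Ymc <- .center(Ymat)
    r2_full <- .r2(Ymc, XZ)
    r2_z <- if (has_z) .r2(Ymc, Zc) else 0
    r2_cond <- r2_full - r2_z
    (r2_cond / m) / ((1 - r2_full) / (n - m - q - 1))
  }
  F_obs <- pseudo_f(Yc)
  set.seed(seed)
  F_perm <- vapply(seq_len(n_perm), function(i) {
    pseudo_f(fit_red + res_red[sample.int(n), , drop = FALSE])
  }, numeric(1))
  p <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)
  r2_full <- .r2(Yc, XZ); r2_z <- if (has_z) .r2(Yc, Zc) else 0
  structure(list(F = F_obs, p = p, n_perm = n_perm,
                 R2_cond = r2_full - r2_z, n = n, m = m, q = q),
            class = "rda_permtest")
}

#' @export
print.rda_permtest <- function(x, ...) {
  cat(sprintf("Permutation test (reduced-model residuals, %d perms): F = %.3f, p = %.4f\n",
              x$n_perm, x$F, x$p))
  invisible(x)
}

#' Lagged variance-partitioning scan
#'
#' Repeats the two-set variance partitioning with the response shifted `k`
#' weeks later than the predictors, for `k` in `lags` (default 0-7), keeping
#' the window size — and hence `n` — identical across all lags. Positive lag
#' means the biology responds `k` weeks after the environmental signal.
#' Permutation p-values for both conditional fractions are Bonferroni-
#' corrected by the number of lags scanned.
#'
#' @param Y response series matrix (rows = weeks, in time order).
#' @param X1,X2 predictor series matrices on the same weekly grid.
#' @param lags integer lags in weeks (default `0:7`).
#' @param n_perm permutations per test.
#' @param seed RNG seed (advanced deterministically per lag).
#' @param transform species transform for `Y`.
#' @return Object of class `lagged_varpart`: data frame `table` (one row per
#'   lag: fractions, adjusted fractions, raw and Bonferroni p for each
#'   conditional fraction, `n`), plus the per-lag `varpart_result`s.
#' @export
lagged_varpart <- function(Y, X1, X2, lags = 0:7, n_perm = 999L, seed = 1L,
                           transform = "standardize") {
  Y <- .as_matrix(Y, "Y"); X1 <- .as_matrix(X1, "X1"); X2 <- .as_matrix(X2, "X2")
  n_total <- nrow(Y)
  max_lag <- max(lags)
  n_use <- n_total - max_lag
  if (n_use < ncol(X1) + ncol(X2) + 3L)
    stop_bloomkit(sprintf(
      "series too short: %d rows leave n = %d after the %d-week window; need > %d",
      n_total, n_use, max_lag, ncol(X1) + ncol(X2) + 2L),
      "bloomkit_window_error")
  resp_rows <- (max_lag + 1L):n_total
  rows <- vector("list", length(lags))
  parts <- vector("list", length(lags))
  n_tests <- length(lags)
  for (i in seq_along(lags)) {
    k <- lags[i]
    pred_rows <- resp_rows - k
    Yk <- Y[resp_rows, , drop = FALSE]
    X1k <- X1[pred_rows, , drop = FALSE]
    X2k <- X2[pred_rows, , drop = FALSE]
    vp <- variance_partition(Yk, X1k, X2k, transform = transform)
    Yt <- transform_species(Yk, transform)
    p1 <- permutation_test(Yt, X1k, X2k, n_perm = n_perm, seed = seed + 2L * i)$p
    p2 <- permutation_test(Yt, X2k, X1k, n_perm = n_perm, seed = seed + 2L * i + 1L)$p
    parts[[i]] <- vp
    rows[[i]] <- data.frame(
      lag = k, n = vp$n,
      a = vp$fractions[["a"]], b = vp$fractions[["b"]],
      c = vp$fractions[["c"]], residual = vp$fractions[["residual"]],
      a_adj = vp$fractions_adj[["a"]], c_adj = vp$fractions_adj[["c"]],
      p_a = p1, p_c = p2,
      p_a_bonf = min(1, n_tests * p1), p_c_bonf = min(1, n_tests * p2))
  }
  structure(list(table = do.call(rbind, rows), parts = parts, lags = lags,
                 lag_convention = "response shifted k weeks after predictors"),
            class = "lagged_varpart")
}

#' @export
print.lagged_varpart <- function(x, ...) {
  cat("Lagged variance-partitioning scan (", x$lag_convention, ")\n", sep = "")
  print.data.frame(x$table, digits = 3, row.names = FALSE)
  best <- x$table$lag[which.max(x$table$c_adj)]
  cat(sprintf("  max adjusted X2-fraction at lag %d wk\n", best))
  invisible(x)
}

#' All-subsets multiple regression of intrinsic growth drivers
#'
#' Ordinary least squares of a univariate response on every subset of the
#' candidate predictors, ranked by AIC. Collinear candidate sets are refused
#' with a diagnostic rather than silently regularized.
#'
#' @param response numeric response vector.
#' @param predictors data frame or matrix of candidate predictors (<= 12).
#' @return Object of class `subset_lm`: `best` (an `lm`), `best_predictors`,
#'   `table` (2^k rows: predictors, k, AIC, delta).
#' @export
intrinsic_driver_regression <- function(response, predictors) {
  X <- .as_matrix(predictors, "predictors")
  if (ncol(X) > 12L)
    stop_bloomkit("at most 12 candidate predictors", "bloomkit_config_error")
  if (length(response) != nrow(X))
    stop_bloomkit("response and predictors differ in length", "bloomkit_data_error")
  .check_rank(X, "predictors")
  k <- ncol(X)
  dat <- data.frame(.y = response, X)
  nm <- colnames(X)
  subsets <- lapply(0:(2^k - 1), function(m) nm[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
  rows <- lapply(subsets, function(s) {
    fml <- stats::as.formula(paste(".y ~", if (length(s)) paste(s, collapse = "+") else "1"))
    data.frame(predictors = paste(s, collapse = "+"), k = length(s),
               AIC = stats::AIC(stats::lm(fml, data = dat)))
  })
  tab <- do.call(rbind, rows)
  tab$delta <- tab$AIC - min(tab$AIC)
  ord <- order(tab$AIC)
  best_s <- subsets[[ord[1]]]
  best_fml <- stats::as.formula(paste(".y ~", if (length(best_s))
    paste(best_s, collapse = "+") else "1"))
  structure(list(best = stats::lm(best_fml, data = dat),
                 best_predictors = best_s,
                 table = `rownames<-`(tab[ord, , drop = FALSE], NULL)),
            class = "subset_lm")
}

#' @export
print.subset_lm <- function(x, ...) {
  cat("All-subsets OLS (", nrow(x$table), " models); best subset: ",
      if (length(x$best_predictors)) paste(x$best_predictors, collapse = " + ")
      else "(intercept only)", "\n", sep = "")
  print(stats::coef(summary(x$best)), digits = 3)
  invisible(x)
}
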