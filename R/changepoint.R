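## within-segment RSS cost matrix: cost[i, j] = RSS of y[i..j]
.segment_cost <- function(y) {
  n <- length(y)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  cost <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    j <- i:n
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    cost[i, j] <- s2 - s^2 / (j - i + 1)
  }
  cost
}

#' Optimal least-squares segmentation into K mean-shift segments
#'
#' Dynamic programme over segment ends minimizing the total within-segment
#' residual sum of squares (the mean-shift contrast), subject to a minimum
#' segment length. The global optimum is guaranteed; cost ties are broken
#' toward the earliest breakpoint so output is deterministic.
#'
#' @param y numeric series.
#' @param K number of segments (`K - 1` breakpoints); must be feasible for
#'   `length(y)` and `min_seg_len`.
#' @param min_seg_len minimum observations per segment (default 2).
#' @return List: `breakpoints` (1-based index of the last element of each of
#'   the first `K - 1` segments), `J` (the optimal contrast), `segment_means`,
#'   `K`.
#' @export
optimal_segmentation <- function(y, K, min_seg_len = 2L) {
  n <- length(y)
  K <- assert_count(K, "K")
  if (K > floor(n / min_seg_len))
    stop_bloomkit(sprintf("K = %d infeasible for n = %d with min segment length %d",
                          K, n, min_seg_len), "bloomkit_feasibility_error")
  all_k <- .segment_dp(y, K, min_seg_len)
  res <- all_k$paths[[K]]
  means <- vapply(seq_len(K), function(s) {
    bounds <- c(0L, res$breaks, n)
    mean(y[(bounds[s] + 1L):bounds[s + 1L]])
  }, numeric(1))
  list(breakpoints = res$breaks, J = res$J, segment_means = means, K = K)
}

## DP for all segment counts 1..K; returns J(k) and breakpoints per k
.segment_dp <- function(y, Kmax, min_seg_len = 2L) {
  n <- length(y)
  cost <- .segment_cost(y)
  # D[k, j]: minimal cost of segmenting y[1..j] into k segments
  D <- matrix(Inf, Kmax, n)
  back <- matrix(NA_integer_, Kmax, n)
  feas1 <- min_seg_len:n
  D[1, feas1] <- cost[1, feas1]
  if (Kmax >= 2L) {
    for (k in 2:Kmax) {
      for (j in seq.int(k * min_seg_len, n)) {
        i_opts <- seq.int((k - 1L) * min_seg_len, j - min_seg_len)
        vals <- D[k - 1L, i_opts] + cost[cbind(i_opts + 1L, j)]
        best <- which.min(vals)  # first minimum: earliest breakpoint wins ties
        D[k, j] <- vals[best]
        back[k, j] <- i_opts[best]
      }
    }
  }
  paths <- lapply(seq_len(Kmax), function(k) {
    if (!is.finite(D[k, n])) return(NULL)
    breaks <- integer(0)
    j <- n
    if (k >= 2L) {
      for (kk in k:2) { j <- back[kk, j]; breaks <- c(j, breaks) }
    }
    list(breaks = breaks, J = D[k, n])
  })
  list(J = D[, n], paths = paths)
}

#' Choose the number of segments by penalized contrast
#'
#' Lavielle-style selection: the optimal contrasts `J(K)` for `K = 1..Kmax`
#' are rescaled to `[1, Kmax]`, the discrete curvature
#' `D(K) = Jn(K-1) - 2 Jn(K) + Jn(K+1)` is computed, and the chosen `K` is
#' the largest one whose curvature exceeds the threshold `S` (default 0.75);
#' if none does, `K = 1` (no breakpoints). A flat series (all `J` equal)
#' yields `K = 1`.
#'
#' @param y numeric series (length >= 2 * `min_seg_len`).
#' @param Kmax maximal number of segments considered (>= 2).
#' @param S curvature threshold.
#' @param min_seg_len minimum segment length.
#' @return List of class `lavielle_selection`: chosen `K`, `J`, normalized
#'   `J_norm`, curvature `D`, `S`.
#' @export
select_K <- function(y, Kmax = min(8L, floor(length(y) / 4)), S = 0.75,
                     min_seg_len = 2L) {
  n <- length(y)
  if (n < 2L * min_seg_len)
    stop_bloomkit("series too short for any breakpoint", "bloomkit_insufficient_data")
  Kmax <- max(2L, min(assert_count(Kmax, "Kmax", min = 2L),
                      floor(n / min_seg_len)))
  J <- .segment_dp(y, Kmax, min_seg_len)$J
  # a (numerically) constant series has nothing to segment; guard before the
  # scale-free normalization amplifies rounding dust in the costs
  degenerate <- stats::sd(y) <= 1e-12 * (abs(mean(y)) + 1)
  if (degenerate || J[1] - J[Kmax] <= 0) {
    out <- list(K = 1L, J = J, J_norm = rep(1, Kmax), D = rep(0, Kmax), S = S)
    class(out) <- "lavielle_selection"
    return(out)
  }
  Jn <- (J[Kmax] - J) / (J[Kmax] - J[1]) * (Kmax - 1) + 1  # decreasing, in [1, Kmax]
  D <- rep(NA_real_, Kmax)
  if (Kmax >= 3L)
    for (k in 2:(Kmax - 1L)) D[k] <- Jn[k - 1L] - 2 * Jn[k] + Jn[k + 1L]
  cand <- which(!is.na(D) & D > S)
  K <- if (length(cand)) max(cand) else 1L
  out <- list(K = K, J = J, J_norm = Jn, D = D, S = S)
  class(out) <- "lavielle_selection"
  out
}

#' Detect mean-shift breakpoints in a phytoplankton series
#'
#' Runs the penalized-contrast selection of the number of segments, then the
#' optimal segmentation at that number. Abundance series spanning orders of
#' magnitude are log-transformed first (`log(x + floor)`, floor = half the
#' smallest positive value) unless `log = FALSE`; breakpoint locations are
#' invariant to that monotone rescaling only insofar as the mean-shift
#' structure is preserved, which is why the transform is applied before, not
#' after, segmentation. Segment means are reported on both scales.
#'
#' @param series a `plankton_ts` data frame or a numeric vector.
#' @param variable column name when `series` is a data frame.
#' @param log log-transform before segmentation (default `TRUE`).
#' @param Kmax,S,min_seg_len see [select_K()].
#' @return Object of class `segmentation`: `K`, `breakpoints` (1-based last
#'   index of each of the first `K - 1` segments), `segment_means` (raw
#'   scale), `segment_means_transformed`, `J`, `selection`.
#' @export
detect_breakpoints <- function(series, variable = NULL, log = TRUE,
                               Kmax = NULL, S = 0.75, min_seg_len = 2L) {
  y_raw <- if (is.data.frame(series)) {
    if (is.null(variable) || !variable %in% names(series))
      stop_bloomkit("`variable` must name a column of `series`", "bloomkit_data_error")
    series[[variable]]
  } else as.numeric(series)
  if (length(y_raw) < 10L)
    stop_bloomkit("need >= 10 samples for breakpoint detection",
                  "bloomkit_insufficient_data")
  if (anyNA(y_raw))
    stop_bloomkit("missing values in series", "bloomkit_data_error")
  y <- y_raw
  if (log) {
    pos <- y_raw[y_raw > 0]
    if (!length(pos))
      stop_bloomkit("all-zero series cannot be log-transformed", "bloomkit_data_error")
    y <- base::log(y_raw + min(pos) / 2)
  }
  Kmax <- Kmax %||% min(8L, floor(length(y) / 4))
  sel <- select_K(y, Kmax = Kmax, S = S, min_seg_len = min_seg_len)
  seg <- optimal_segmentation(y, sel$K, min_seg_len = min_seg_len)
  bounds <- c(0L, seg$breakpoints, length(y))
  means_raw <- vapply(seq_len(sel$K), function(s)
    mean(y_raw[(bounds[s] + 1L):bounds[s + 1L]]), numeric(1))
  structure(list(K = sel$K, breakpoints = seg$breakpoints,
                 segment_means = means_raw,
                 segment_means_transformed = seg$segment_means,
                 J = sel$J, selection = sel, variable = variable,
                 log = log),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("Penalized-contrast segmentation%s: %d segment(s)\n",
              if (!is.null(x$variable)) paste0(" of `", x$variable, "`") else "",
              x$K))
  if (length(x$breakpoints))
    cat("  breakpoints after indices:", paste(x$breakpoints, collapse = ", "), "\n")
  cat("  segment means:", paste(signif(x$segment_means, 4), collapse = ", "), "\n")
  invisible(x)
}
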