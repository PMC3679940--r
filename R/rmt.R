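# Random Matrix Theory thresholding.
#
# The correlation threshold is chosen at the transition of the thresholded
# matrix's eigenvalue nearest-neighbor spacing distribution (NNSD): a matrix
# dominated by modular biological signal has Poisson (exponential) spacings,
# while one dominated by noise shows Gaussian-Orthogonal-Ensemble level
# repulsion (Wigner surmise). Scanning the threshold downward, the last value
# before the NNSD stops looking Poisson is the chosen cutoff.

#' Unfold a spectrum to unit mean spacing
#'
#' Removes the smooth part of the spectral density so that only fluctuation
#' statistics remain: a monotone cubic spline is fit through every
#' `fit_knots`-th point of the empirical cumulative spectral count and the
#' eigenvalues are mapped through it, then rescaled so the mean
#' nearest-neighbor spacing is exactly 1. Eigenvalues are deduplicated at
#' tolerance `dedup_tol` first (degenerate eigenvalues would contribute
#' spurious zero spacings).
#'
#' @param eigenvalues numeric vector (any order).
#' @param fit_knots spline knot pace (default every 10th point).
#' @param dedup_tol deduplication tolerance (default 1e-8).
#' @param min_distinct minimum number of distinct eigenvalues required
#'   (default 100; below this the NNSD test is meaningless).
#' @return Increasing numeric vector of unfolded eigenvalues, one per
#'   distinct input eigenvalue.
#' @export
unfold_eigenvalues <- function(eigenvalues, fit_knots = 10L,
                               dedup_tol = 1e-8, min_distinct = 100L) {
  ev <- sort(eigenvalues)
  ev <- ev[c(TRUE, diff(ev) > dedup_tol)]
  n <- length(ev)
  if (n < min_distinct) {
    unbuildable(sprintf("too few distinct eigenvalues (%d < %d)",
                        n, min_distinct))
  }
  knots <- unique(c(seq(1L, n, by = fit_knots), n))
  sf <- splinefun(ev[knots], knots, method = "hyman")
  u <- sf(ev)
  (u - u[1]) / (u[n] - u[1]) * (n - 1)
}

#' Chi-square statistic of the NNSD against the Poisson law
#'
#' Spacings `s_i = e_{i+1} - e_i` of the unfolded spectrum are histogrammed on
#' `n_bins` equal bins over `[0, s_max]`; expected counts under the Poisson
#' (exponential, unit-mean) spacing law are
#' `E_b = N * (exp(-lo_b) - exp(-hi_b))`. Returns
#' `sum((O_b - E_b)^2 / E_b)` over bins with positive expectation. Large
#' values reject the Poisson null (GOE-like level repulsion).
#'
#' @param unfolded unfolded eigenvalues (at least 2).
#' @param n_bins histogram bins (default 60).
#' @param s_max histogram upper limit (default 3).
#' @return The chi-square statistic (single number).
#' @export
nnsd_chi_square <- function(unfolded, n_bins = 60L, s_max = 3) {
  stopifnot(length(unfolded) >= 2)
  s <- diff(sort(unfolded))
  breaks <- seq(0, s_max, length.out = n_bins + 1L)
  bin <- findInterval(s, breaks, rightmost.closed = FALSE)
  O <- tabulate(bin[bin >= 1L & bin <= n_bins], nbins = n_bins)
  E <- length(s) * (exp(-breaks[-length(breaks)]) - exp(-breaks[-1]))
  sum((O - E)^2 / E)
}

#' Choose a correlation threshold by an RMT scan
#'
#' Scans `t` from `t_start` downward by `step` to `t_stop`. At each `t` the
#' similarity matrix is reduced to the rows/columns with at least one
#' off-diagonal `|r| >= t`, entries below `t` are zeroed, the diagonal is set
#' to 1, and the NNSD chi-square of the unfolded spectrum is computed. The
#' chosen threshold is the last scanned `t` before the first chi-square
#' exceedance of `chi_crit` — i.e. the smallest `t` such that every usable
#' scan point at or above it is Poisson-like. Scan points with fewer than
#' `min_eigenvalues` retained rows or distinct eigenvalues are recorded but
#' not testable.
#'
#' Failure modes mirror networks that "did not construct": if the very first
#' usable scan point already exceeds `chi_crit` the result is
#' `"never Poisson-like"`; if no scan point is usable at all it is
#' `"matrix too small"`.
#'
#' @param S a `SimilarityMatrix` (or plain symmetric matrix with dimnames).
#' @param t_start,t_stop,step scan bounds and step (defaults 0.99, 0.50,
#'   0.001).
#' @param chi_crit chi-square critical value (default 99.607, the 0.001
#'   upper-tail point at 60 degrees of freedom).
#' @param min_eigenvalues minimum retained dimension / distinct eigenvalues.
#' @param fit_knots,dedup_tol unfolding controls (see
#'   [unfold_eigenvalues()]).
#' @param n_bins,s_max NNSD histogram controls (see [nnsd_chi_square()]).
#' @return An `RMTResult`: list with `threshold` (chosen `t*`, or `NA` on
#'   failure), `success`, `failure_reason`, and `scan` (data frame of `t`,
#'   `retained_dim`, `n_unique_eigenvalues`, `chi_square`).
#' @export
rmt_threshold <- function(S, t_start = 0.99, t_stop = 0.50, step = 0.001,
                          chi_crit = 99.607, min_eigenvalues = 100L,
                          fit_knots = 10L, dedup_tol = 1e-8,
                          n_bins = 60L, s_max = 3) {
  stopifnot(t_start > t_stop, step > 0)
  A <- abs(unclass(S))
  diag(A) <- 0
  row_max <- apply(A, 1, max)
  thresholds <- seq(t_start, t_stop, by = -step)
  scan <- data.frame(t = thresholds, retained_dim = NA_integer_,
                     n_unique_eigenvalues = NA_integer_,
                     chi_square = NA_real_)
  last_usable_t <- NA_real_
  chosen <- NA_real_
  failure <- NA_character_
  for (i in seq_along(thresholds)) {
    t <- thresholds[i]
    keep <- row_max >= t
    dim_t <- sum(keep)
    scan$retained_dim[i] <- dim_t
    if (dim_t < min_eigenvalues) next
    M <- unclass(S)[keep, keep, drop = FALSE]
    M[abs(M) < t] <- 0
    diag(M) <- 1
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    ev_s <- sort(ev)
    distinct <- sum(c(TRUE, diff(ev_s) > dedup_tol))
    scan$n_unique_eigenvalues[i] <- distinct
    if (distinct < min_eigenvalues) next
    u <- unfold_eigenvalues(ev_s, fit_knots = fit_knots,
                            dedup_tol = dedup_tol,
                            min_distinct = min_eigenvalues)
    chi <- nnsd_chi_square(u, n_bins = n_bins, s_max = s_max)
    scan$chi_square[i] <- chi
    if (chi <= chi_crit) {
      last_usable_t <- t
    } else if (is.na(last_usable_t)) {
      failure <- "never Poisson-like"
      break
    } else {
      chosen <- last_usable_t
      break
    }
  }
  if (is.na(chosen) && is.na(failure)) {
    if (!is.na(last_usable_t)) {
      chosen <- last_usable_t  # Poisson-like down to t_stop
    } else {
      failure <- "matrix too small"
    }
  }
  structure(list(
    threshold = chosen,
    success = !is.na(chosen),
    failure_reason = failure,
    scan = scan[!is.na(scan$retained_dim), , drop = FALSE]
  ), class = "RMTResult")
}

#' @export
print.RMTResult <- function(x, ...) {
  if (x$success) {
    cat(sprintf("RMTResult: threshold %.3f (%d scan points)\n",
                x$threshold, nrow(x$scan)))
  } else {
    cat(sprintf("RMTResult: failed (%s)\n", x$failure_reason))
  }
  invisible(x)
}
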