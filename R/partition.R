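#' Partition samples into K clusters by K-means on expression profiles
#'
#' Samples are points in gene-expression space (Euclidean distance over all
#' genes, no gene standardization by default — clustering is by similarity of
#' raw normalized expression values). Lloyd's algorithm is run from `n_init`
#' random initializations and the assignment with the lowest inertia (sum of
#' squared distances to centroids) is kept. Empty clusters are re-seeded from
#' the point farthest from its centroid. Deterministic given `seed`.
#'
#' @param X an [expression_matrix()] without missing values.
#' @param K number of clusters, at most the number of samples.
#' @param seed integer seed.
#' @param n_init number of random restarts (default 10).
#' @param max_iter Lloyd iteration cap (default 300); non-convergence warns
#'   and returns the current assignment.
#' @param standardize scale each gene to unit variance first (off by default).
#' @return A `SamplePartition`: list with `K`, `assignment` (named integer in
#'   `1..K`), `inertia`, `seed`, and `iter_inertia` (per-iteration inertia of
#'   the winning run, non-increasing).
#' @export
kmeans_partition <- function(X, K, seed = 1L, n_init = 10L, max_iter = 300L,
                             standardize = FALSE) {
  stopifnot(is_count(K), K >= 1)
  pts <- t(unclass(X))
  if (anyNA(pts)) stop("kmeans_partition requires a complete matrix")
  m <- nrow(pts)
  if (K > m) stop(sprintf("K = %d exceeds the number of samples (%d)", K, m))
  if (standardize) {
    sdv <- apply(pts, 2, sd)
    sdv[sdv == 0] <- 1
    pts <- sweep(pts, 2, sdv, "/")
  }
  set.seed(seed)
  pts_sq <- rowSums(pts^2)
  best <- NULL
  for (init in seq_len(n_init)) {
    centers <- pts[sample.int(m, K), , drop = FALSE]
    assign_prev <- integer(m)
    trace <- numeric(0)
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      d2 <- outer(pts_sq, rowSums(centers^2), "+") - 2 * pts %*% t(centers)
      d2[d2 < 0] <- 0
      assignment <- max.col(-d2, ties.method = "first")
      # re-seed empty clusters from the farthest point
      own <- d2[cbind(seq_len(m), assignment)]
      for (k in setdiff(seq_len(K), unique(assignment))) {
        far <- which.max(own)
        assignment[far] <- k
        own[far] <- 0
      }
      d_assigned <- d2[cbind(seq_len(m), assignment)]
      trace <- c(trace, sum(d_assigned))
      if (identical(assignment, assign_prev)) {
        converged <- TRUE
        break
      }
      assign_prev <- assignment
      centers <- cluster_centers(pts, assignment, K)
    }
    if (!converged) {
      warning(sprintf("Lloyd iteration cap (%d) reached for init %d",
                      max_iter, init))
    }
    # final inertia against the centroids of the final assignment
    centers <- cluster_centers(pts, assignment, K)
    d2 <- outer(pts_sq, rowSums(centers^2), "+") - 2 * pts %*% t(centers)
    inertia <- sum(pmax(d2[cbind(seq_len(m), assignment)], 0))
    if (is.null(best) || inertia < best$inertia) {
      best <- list(assignment = assignment, inertia = inertia, trace = trace)
    }
  }
  structure(list(
    K = as.integer(K),
    assignment = stats::setNames(best$assignment, rownames(pts)),
    inertia = best$inertia,
    seed = as.integer(seed),
    iter_inertia = best$trace
  ), class = "SamplePartition")
}

cluster_centers <- function(pts, assignment, K) {
  counts <- as.vector(table(factor(assignment, levels = seq_len(K))))
  centers <- matrix(0, K, ncol(pts))
  present <- sort(unique(assignment))
  centers[present, ] <- rowsum(pts, assignment) / counts[present]
  # a cluster emptied by re-seeding keeps a copy of the global farthest point
  if (any(counts == 0)) {
    overall <- colMeans(pts)
    far <- which.max(rowSums(sweep(pts, 2, overall)^2))
    centers[counts == 0, ] <- matrix(pts[far, ], sum(counts == 0),
                                     ncol(pts), byrow = TRUE)
  }
  centers
}

#' @export
print.SamplePartition <- function(x, ...) {
  cat(sprintf("SamplePartition: %d samples in K = %d clusters (inertia %.4g)\n",
              length(x$assignment), x$K, x$inertia))
  invisible(x)
}

#' Randomize a partition while preserving cluster sizes
#'
#' Selects `floor(fraction * m)` samples uniformly without replacement and
#' permutes their cluster labels among themselves with a uniform random
#' permutation. The multiset of cluster sizes is preserved exactly (cluster
#' number and sizes intact); `fraction = 0` is the identity. Deterministic
#' given `seed`.
#'
#' @param P a `SamplePartition`.
#' @param fraction fraction of samples to re-assign, in \[0, 1\].
#' @param seed integer seed.
#' @return A new `SamplePartition` (inertia is dropped: it no longer
#'   corresponds to a K-means solution).
#' @export
randomize_partition <- function(P, fraction, seed = 1L) {
  stopifnot(inherits(P, "SamplePartition"))
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must be in [0, 1]")
  }
  m <- length(P$assignment)
  n_move <- floor(fraction * m)
  assignment <- P$assignment
  if (n_move >= 2) {
    set.seed(seed)
    idx <- sample.int(m, n_move)
    assignment[idx] <- assignment[idx][sample.int(n_move)]
  }
  structure(list(K = P$K, assignment = assignment, inertia = NA_real_,
                 seed = as.integer(seed), iter_inertia = numeric(0)),
            class = "SamplePartition")
}
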