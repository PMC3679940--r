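#' Remove control probes by identifier prefix
#'
#' Drops rows whose identifier starts with any of `control_prefixes`
#' (Affymetrix control probes start with `"AFFX"`). Row order of the retained
#' probes is preserved; zero removals are allowed.
#'
#' @param X an [expression_matrix()].
#' @param control_prefixes character vector of prefixes.
#' @return The reduced [expression_matrix()].
#' @export
drop_control_probes <- function(X, control_prefixes = "AFFX") {
  if (length(control_prefixes) == 0) return(X)
  is_control <- Reduce(`|`, lapply(control_prefixes, startsWith,
                                   x = rownames(X)))
  keep <- unclass(X)[!is_control, , drop = FALSE]
  expression_matrix(keep, rownames(X)[!is_control], colnames(X))
}

#' Quantile normalization across samples
#'
#' Forces every column to share the same value distribution: the sorted value
#' vector of each column becomes the vector of row-rank means, with ties
#' resolved by average rank (fractional ranks are linearly interpolated
#' between adjacent rank means). Missing cells are row-mean imputed first,
#' with a warning.
#'
#' @param X an [expression_matrix()] with at least two samples.
#' @return The normalized [expression_matrix()].
#' @export
quantile_normalize <- function(X) {
  if (nrow(X) == 0) stop("empty expression matrix")
  if (ncol(X) < 2) stop("quantile normalization requires at least 2 samples")
  V <- unclass(X)
  if (anyNA(V)) {
    warning("missing values row-mean imputed before quantile normalization")
    rm <- rowMeans(V, na.rm = TRUE)
    idx <- which(is.na(V), arr.ind = TRUE)
    V[idx] <- rm[idx[, 1]]
    if (anyNA(V)) stop("rows with all values missing cannot be normalized")
  }
  ref <- rowMeans(apply(V, 2, sort))
  out <- apply(V, 2, function(col) {
    r <- rank(col, ties.method = "average")
    (ref[floor(r)] + ref[ceiling(r)]) / 2
  })
  expression_matrix(out, rownames(X), colnames(X))
}

#' Detect outlier samples within a cluster
#'
#' Three per-sample scores stand in for the three array-quality outlier tests:
#' (1) mean inter-sample distance `1 - r` (Pearson) to all other samples,
#' (2) the Kolmogorov-Smirnov statistic of the sample's value distribution
#' against the pooled distribution of all samples, and (3) the median absolute
#' deviation of the sample from the row-median pseudo-reference. Each score is
#' flagged when it exceeds the Tukey fence `Q3 + 1.5 * IQR` across samples; a
#' sample is removed iff it fails at least two of the three tests.
#'
#' @param X an [expression_matrix()] with at least 4 samples (outlier
#'   statistics are meaningless below that).
#' @return Data frame (class `OutlierReport`): one row per sample with the
#'   three scores, the three flags, and `removed`.
#' @export
detect_outlier_samples <- function(X) {
  if (ncol(X) < 4) stop("outlier detection requires at least 4 samples")
  V <- unclass(X)
  m <- ncol(V)
  cm <- suppressWarnings(cor(V, use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  dist_score <- rowSums(1 - cm) / (m - 1)  # diagonal contributes 0
  pooled <- as.vector(V)
  ks_score <- vapply(seq_len(m), function(j) {
    suppressWarnings(unname(ks.test(V[, j], pooled)$statistic))
  }, numeric(1))
  ref <- apply(V, 1, median, na.rm = TRUE)
  mad_score <- vapply(seq_len(m), function(j) {
    median(abs(V[, j] - ref), na.rm = TRUE)
  }, numeric(1))
  flag <- function(s) {
    q <- quantile(s, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
    s > q[2] + 1.5 * (q[2] - q[1])
  }
  rep <- data.frame(
    sample_id = colnames(V),
    dist_score = dist_score, ks_score = ks_score, mad_score = mad_score,
    dist_flag = flag(dist_score), ks_flag = flag(ks_score),
    mad_flag = flag(mad_score),
    stringsAsFactors = FALSE
  )
  rep$removed <- rowSums(rep[c("dist_flag", "ks_flag", "mad_flag")]) >= 2
  class(rep) <- c("OutlierReport", "data.frame")
  rep
}

#' Remove outlier samples flagged by [detect_outlier_samples()]
#' @param X an [expression_matrix()].
#' @param report an `OutlierReport` for `X` (computed if omitted).
#' @return The reduced [expression_matrix()].
#' @export
drop_outlier_samples <- function(X, report = detect_outlier_samples(X)) {
  keep <- !report$removed[match(colnames(X), report$sample_id)]
  expression_matrix(unclass(X)[, keep, drop = FALSE],
                    rownames(X), colnames(X)[keep])
}

#' Remove unmapped and ambiguous probes
#'
#' Keeps exactly the rows whose probe maps to exactly one gene; probes mapping
#' to no gene (unmapped) or to more than one (ambiguous, potentially
#' hybridizing to multiple genes) are removed.
#'
#' @param X an [expression_matrix()] with probe-level row identifiers.
#' @param map probe-to-gene map as returned by [read_probe_gene_map()].
#' @return The reduced [expression_matrix()].
#' @export
drop_ambiguous_probes <- function(X, map) {
  n_map <- vapply(rownames(X), function(p) {
    g <- map[[p]]
    if (is.null(g)) 0L else length(g)
  }, integer(1))
  keep <- n_map == 1L
  expression_matrix(unclass(X)[keep, , drop = FALSE],
                    rownames(X)[keep], colnames(X))
}
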