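#' Pairwise Pearson similarity matrix
#'
#' `r_ij = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2))`
#' over pairwise-complete samples. Rows with more than `max_missing_frac`
#' missing values are dropped first (logged), as are zero-variance rows
#' (constant genes have undefined correlation). Clusters with fewer than
#' `min_samples` samples are unbuildable — the per-cluster mirror of networks
#' reported "n.a.".
#'
#' @param X an [expression_matrix()].
#' @param min_samples minimum number of samples (default 10).
#' @param max_missing_frac maximum tolerated per-row missing fraction.
#' @return A symmetric `SimilarityMatrix` (unit diagonal, values in \[-1,1\])
#'   with attribute `n_samples`.
#' @export
pearson_matrix <- function(X, min_samples = 10L, max_missing_frac = 0.2) {
  if (ncol(X) < min_samples) {
    unbuildable(sprintf("too few samples (%d < %d)", ncol(X), min_samples))
  }
  V <- unclass(X)
  miss <- rowMeans(is.na(V))
  if (any(miss > max_missing_frac)) {
    message(sprintf("dropping %d row(s) with > %.0f%% missing values",
                    sum(miss > max_missing_frac), 100 * max_missing_frac))
    V <- V[miss <= max_missing_frac, , drop = FALSE]
  }
  vr <- apply(V, 1, function(x) stats::var(x, na.rm = TRUE))
  if (any(vr == 0 | is.na(vr))) {
    warning(sprintf("dropping %d zero-variance row(s)", sum(vr == 0 | is.na(vr))))
    V <- V[!(vr == 0 | is.na(vr)), , drop = FALSE]
  }
  if (nrow(V) < 2) unbuildable("fewer than 2 usable rows")
  S <- suppressWarnings(cor(t(V), use = "pairwise.complete.obs"))
  S[is.na(S)] <- 0  # pairs with no overlapping samples
  S[S > 1] <- 1
  S[S < -1] <- -1
  diag(S) <- 1
  structure(S, n_samples = ncol(V), class = c("SimilarityMatrix", "matrix",
                                              "array"))
}

#' @export
print.SimilarityMatrix <- function(x, ...) {
  cat(sprintf("SimilarityMatrix: %d ids over %d samples\n", nrow(x),
              attr(x, "n_samples")))
  invisible(x)
}

#' Construct a co-expression network from an edge table
#'
#' @param edges data frame with columns `a`, `b` (gene ids) and `r`
#'   (correlation). Pairs are canonicalized (`a < b`), duplicates and
#'   self-edges are errors.
#' @param threshold the correlation threshold the edges satisfy.
#' @param provenance free-form list (cluster id, sample ids, K, seed, ...).
#' @return A `CoexpressionNetwork`: list with `nodes` (sorted ids with degree
#'   >= 1), `edges`, `threshold`, `provenance`.
#' @export
coexpression_network <- function(edges, threshold = NA_real_,
                                 provenance = list()) {
  stopifnot(all(c("a", "b", "r") %in% names(edges)))
  if (nrow(edges) > 0) {
    canon <- canonical_pairs(edges$a, edges$b)
    edges$a <- canon$a
    edges$b <- canon$b
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
    if (anyDuplicated(edge_key(edges$a, edges$b))) {
      stop("duplicate edges after canonicalization")
    }
  }
  structure(list(
    nodes = sort(unique(c(edges$a, edges$b))),
    edges = edges[c("a", "b", "r")],
    threshold = threshold,
    provenance = provenance
  ), class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat(sprintf("CoexpressionNetwork: %d nodes, %d edges (threshold %s)\n",
              length(x$nodes), nrow(x$edges), format(x$threshold)))
  invisible(x)
}

#' Extract the thresholded network from a similarity matrix
#'
#' Keeps an edge for every pair with `|r| >= t` (the signed correlation is
#' preserved as the edge value); nodes with no surviving edge are excluded.
#'
#' @param S a `SimilarityMatrix`.
#' @param t threshold in (0, 1].
#' @param provenance provenance list stored on the network.
#' @return A [coexpression_network()].
#' @export
extract_network <- function(S, t, provenance = list()) {
  stopifnot(t > 0, t <= 1)
  ids <- rownames(S)
  idx <- which(abs(S) >= t & upper.tri(S), arr.ind = TRUE)
  edges <- data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]],
                      r = S[idx], stringsAsFactors = FALSE)
  coexpression_network(edges, threshold = t, provenance = provenance)
}

#' Collapse a probe-level network to a gene-level network
#'
#' Every node must map to exactly one gene (run [drop_ambiguous_probes()]
#' upstream). When several probe pairs collapse onto one gene pair the edge
#' with maximum `|r|` is kept; pairs of probes for the same gene are dropped.
#'
#' @param net a probe-level [coexpression_network()].
#' @param map probe-to-gene map ([read_probe_gene_map()]).
#' @return A gene-level [coexpression_network()].
#' @export
collapse_probes_to_genes <- function(net, map) {
  gene_of <- vapply(net$nodes, function(p) {
    g <- map[[p]]
    if (is.null(g) || length(g) != 1) {
      stop("node not mapped to exactly one gene: ", p)
    }
    g
  }, character(1))
  e <- net$edges
  if (nrow(e) == 0) {
    return(coexpression_network(e, net$threshold, net$provenance))
  }
  ga <- gene_of[e$a]
  gb <- gene_of[e$b]
  keep <- ga != gb  # two probes of one gene: self-pair, dropped
  e <- data.frame(a = ga[keep], b = gb[keep], r = e$r[keep],
                  stringsAsFactors = FALSE)
  if (nrow(e) > 0) {
    canon <- canonical_pairs(e$a, e$b)
    e$a <- canon$a
    e$b <- canon$b
    key <- edge_key(e$a, e$b)
    e <- e[order(key, -abs(e$r), e$r), , drop = FALSE]
    e <- e[!duplicated(edge_key(e$a, e$b)), , drop = FALSE]
  }
  coexpression_network(e, net$threshold, net$provenance)
}
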