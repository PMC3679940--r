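#' Markov clustering (MCL) of a co-expression network
#'
#' Flow simulation on the graph: a column-stochastic matrix is built from the
#' edge weights `|r|` plus unit self-loops, then expansion (matrix square) and
#' inflation (entrywise power, column renormalization) alternate, pruning
#' entries below `pruning`, until the matrix is idempotent
#' (`max |delta| < 1e-8`) or `max_iter` is reached (warn, cluster the current
#' support). Clusters are the connected components of the attractor support;
#' every node belongs to exactly one cluster.
#'
#' @param net a non-empty [coexpression_network()].
#' @param inflation inflation exponent (default 2.0).
#' @param pruning entries below this are zeroed each iteration (default 1e-5).
#' @param max_iter iteration cap (default 100).
#' @param use_weights use `|r|` as edge weight (default); otherwise binary.
#' @return A `ModuleSet`: list with `method = "mcl"` and `modules`, a named
#'   list of gene sets partitioning the node set.
#' @export
mcl <- function(net, inflation = 2, pruning = 1e-5, max_iter = 100L,
                use_weights = TRUE) {
  if (nrow(net$edges) == 0) stop("mcl requires a non-empty network")
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  w <- if (use_weights) abs(net$edges$r) else rep(1, nrow(net$edges))
  A[cbind(net$edges$a, net$edges$b)] <- w
  A[cbind(net$edges$b, net$edges$a)] <- w
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Mn <- M %*% M               # expansion
    Mn <- Mn^inflation          # inflation
    Mn[Mn < pruning] <- 0
    cs <- colSums(Mn)
    cs[cs == 0] <- 1
    Mn <- sweep(Mn, 2, cs, "/")
    delta <- max(abs(Mn - M))
    M <- Mn
    if (delta < 1e-8) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("MCL did not converge; clustering current support")
  support <- (M + t(M)) > 0
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  modules <- split(nodes, memb)
  names(modules) <- sprintf("MCL%04d", seq_along(modules))
  structure(list(method = "mcl", modules = modules), class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  cat(sprintf("ModuleSet (%s): %d modules\n", x$method, length(x$modules)))
  invisible(x)
}

# Jaccard similarity of inclusive neighborhoods, for edges e_ik, e_jk sharing
# node k: S = |n+(i) & n+(j)| / |n+(i) | n+(j)| with n+(x) = {x} + neighbors(x).
link_similarity_dist <- function(edges, nodes) {
  m <- nrow(edges)
  nbr <- vector("list", length(nodes))
  names(nbr) <- nodes
  for (v in nodes) nbr[[v]] <- v
  for (i in seq_len(m)) {
    nbr[[edges$a[i]]] <- c(nbr[[edges$a[i]]], edges$b[i])
    nbr[[edges$b[i]]] <- c(nbr[[edges$b[i]]], edges$a[i])
  }
  incident <- split(rep(seq_len(m), 2L), c(edges$a, edges$b))
  D <- matrix(1, m, m)
  diag(D) <- 0
  for (k in names(incident)) {
    eidx <- incident[[k]]
    if (length(eidx) < 2) next
    other <- ifelse(edges$a[eidx] == k, edges$b[eidx], edges$a[eidx])
    for (p in seq_len(length(eidx) - 1L)) {
      np <- nbr[[other[p]]]
      for (q in seq((p + 1L), length(eidx))) {
        nq <- nbr[[other[q]]]
        s <- length(intersect(np, nq)) / length(union(np, nq))
        d <- 1 - s
        if (d < D[eidx[p], eidx[q]]) {
          D[eidx[p], eidx[q]] <- d
          D[eidx[q], eidx[p]] <- d
        }
      }
    }
  }
  D
}

# partition density of an edge partition: D = (2/M) * sum_c m_c (m_c - (n_c-1))
# / ((n_c-2)(n_c-1)), communities with n_c <= 2 contributing 0.
partition_density <- function(edge_membership, edges) {
  M <- nrow(edges)
  total <- 0
  for (idx in split(seq_len(M), edge_membership)) {
    m_c <- length(idx)
    n_c <- length(unique(c(edges$a[idx], edges$b[idx])))
    if (n_c > 2) {
      total <- total + m_c * (m_c - (n_c - 1)) / ((n_c - 2) * (n_c - 1))
    }
  }
  2 * total / M
}

#' Link-community detection
#'
#' Edges are clustered by single-linkage hierarchical clustering of
#' `1 - S`, where `S` is the Jaccard similarity of the inclusive
#' neighborhoods of the non-shared endpoints of two edges sharing a node
#' (non-adjacent edge pairs have similarity 0 and can only merge by
#' chaining). The dendrogram is cut at the height maximizing the partition
#' density `D`, ties broken toward the lower height. Edge communities
#' partition the edge set; genes may appear in several modules.
#'
#' @param net a non-empty [coexpression_network()].
#' @return A `LinkCommunityResult`: list with `module_set` (a `ModuleSet`
#'   with `method = "lcm"`, gene sets and the matching `edge_modules`),
#'   `partition_density`, `cut_height` and `merges` (dendrogram merge list
#'   with heights).
#' @export
link_communities <- function(net) {
  e <- net$edges
  M <- nrow(e)
  if (M == 0) stop("link_communities requires a non-empty network")
  if (M == 1) {
    ms <- structure(list(method = "lcm",
                         modules = list(LCM0001 = sort(c(e$a, e$b))),
                         edge_modules = list(LCM0001 = 1L)),
                    class = "ModuleSet")
    return(structure(list(module_set = ms, partition_density = 0,
                          cut_height = 0, merges = NULL),
                     class = "LinkCommunityResult"))
  }
  D <- link_similarity_dist(e, net$nodes)
  hc <- hclust(as.dist(D), method = "single")
  heights <- sort(unique(c(0, hc$height)))
  best_d <- -Inf
  best_h <- heights[1]
  best_memb <- NULL
  for (h in heights) {
    memb <- cutree(hc, h = h)
    d <- partition_density(memb, e)
    if (d > best_d) {  # strict: ties keep the lower height
      best_d <- d
      best_h <- h
      best_memb <- memb
    }
  }
  groups <- split(seq_len(M), best_memb)
  names(groups) <- sprintf("LCM%04d", seq_along(groups))
  modules <- lapply(groups, function(idx) sort(unique(c(e$a[idx], e$b[idx]))))
  ms <- structure(list(method = "lcm", modules = modules,
                       edge_modules = groups),
                  class = "ModuleSet")
  structure(list(
    module_set = ms,
    partition_density = best_d,
    cut_height = best_h,
    merges = data.frame(hc$merge, height = hc$height)
  ), class = "LinkCommunityResult")
}

#' @export
print.LinkCommunityResult <- function(x, ...) {
  cat(sprintf("LinkCommunityResult: %d communities, D = %.4f at height %.4f\n",
              length(x$module_set$modules), x$partition_density, x$cut_height))
  invisible(x)
}

#' Summaries of a module set
#'
#' Module count, median/min/max gene-set size, and gene coverage (fraction of
#' network nodes appearing in at least one counted module). For link
#' communities, single-edge communities are excluded from the statistics
#' (`min_edges = 2`); MCL partitions count every cluster.
#'
#' @param ms a `ModuleSet`.
#' @param n_nodes number of nodes in the source network (for coverage; `NA`
#'   if omitted).
#' @param min_edges minimum edge count for an LCM community to count as a
#'   module.
#' @return List with `count`, `median_size`, `min_size`, `max_size`,
#'   `coverage` (all `NA`-safe for empty sets).
#' @export
module_size_stats <- function(ms, n_nodes = NA_integer_, min_edges = 2L) {
  modules <- ms$modules
  if (identical(ms$method, "lcm") && !is.null(ms$edge_modules)) {
    modules <- modules[lengths(ms$edge_modules) >= min_edges]
  }
  sizes <- lengths(modules)
  if (length(sizes) == 0) {
    return(list(count = 0L, median_size = NA_real_, min_size = NA_integer_,
                max_size = NA_integer_, coverage = NA_real_))
  }
  list(
    count = length(sizes),
    median_size = median(sizes),
    min_size = min(sizes),
    max_size = max(sizes),
    coverage = if (is.na(n_nodes)) NA_real_ else
      length(unique(unlist(modules, use.names = FALSE))) / n_nodes
  )
}
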