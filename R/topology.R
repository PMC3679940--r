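#' Basic degree statistics of a network
#'
#' @param net a non-empty [coexpression_network()].
#' @return List with `n_nodes`, `n_edges`, `avg_degree` (`2m/n`, unrounded)
#'   and the named integer `degrees` vector.
#' @export
degree_stats <- function(net) {
  if (nrow(net$edges) == 0) stop("degree_stats requires a non-empty network")
  deg <- table(factor(c(net$edges$a, net$edges$b), levels = net$nodes))
  n <- length(net$nodes)
  m <- nrow(net$edges)
  list(n_nodes = n, n_edges = m, avg_degree = 2 * m / n,
       degrees = stats::setNames(as.integer(deg), names(deg)))
}

#' Average degree from node and edge counts
#'
#' `2m/n`, rounded at report time only: two decimals in the per-layer table
#' style, integers in the global-summary style.
#'
#' @param n_nodes,n_edges counts.
#' @param digits decimals to round to (default 2; use 0 for the global style).
#' @export
#' @examples
#' average_degree(3297, 129134, digits = 0)  # 78
#' average_degree(1921, 7807)                # 8.13
average_degree <- function(n_nodes, n_edges, digits = 2) {
  round(2 * n_edges / n_nodes, digits)
}

#' Maximum-likelihood scale-free exponent
#'
#' Continuous-approximation MLE for the power-law exponent of a degree
#' sequence: `gamma_hat = 1 + n_tail / sum(log(x / (xmin - 0.5)))` over the
#' tail sample `x >= xmin`. Values below `xmin` never affect the estimate.
#'
#' @param degrees positive integer degree sequence.
#' @param xmin smallest degree included in the tail; defaults to the smallest
#'   observed degree >= 1.
#' @param min_tail smallest tail sample accepted (default 10; lower it
#'   explicitly for toy closed-form checks).
#' @return `gamma_hat` (single number).
#' @export
fit_power_law <- function(degrees, xmin = NULL, min_tail = 10L) {
  x <- degrees[degrees >= 1]
  if (is.null(xmin)) xmin <- min(x)
  stopifnot(xmin >= 1)
  tail <- x[x >= xmin]
  if (length(tail) < min_tail) {
    stop(sprintf("need at least %d values >= xmin", min_tail))
  }
  if (length(unique(tail)) == 1) {
    stop("all tail values equal: exponent undefined")
  }
  1 + length(tail) / sum(log(tail / (xmin - 0.5)))
}

#' Mean local clustering coefficient
#'
#' Mean over nodes of `2 * triangles / (deg * (deg - 1))`; nodes of degree
#' below 2 contribute 0.
#'
#' @param net a non-empty [coexpression_network()].
#' @return Single number in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  if (nrow(net$edges) == 0) stop("clustering_coefficient requires edges")
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  A[cbind(net$edges$a, net$edges$b)] <- 1
  A[cbind(net$edges$b, net$edges$a)] <- 1
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  cc <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
  mean(cc)
}
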