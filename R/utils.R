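#' Canonicalize unordered gene pairs
#'
#' Orders each pair lexicographically (`a < b`) so that edge-set comparisons
#' are independent of construction order. Self-pairs are not allowed.
#'
#' @param a,b character vectors of endpoint identifiers.
#' @return A data frame with columns `a` and `b`, `a < b` row-wise.
#' @keywords internal
canonical_pairs <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a == b)) stop("self-pairs are not allowed")
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

edge_key <- function(a, b) paste(a, b, sep = "\r")

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label names), ~0 for independent ones.
#'
#' @param x,y label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  tab <- table(x, y)
  n <- length(x)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  total <- n * (n - 1) / 2
  expected <- sum_i * sum_j / total
  maximum <- (sum_i + sum_j) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

# classed error used for clusters that cannot yield a network ("n.a." GILs)
unbuildable <- function(reason) {
  stop(structure(
    class = c("gilnet_unbuildable", "error", "condition"),
    list(message = reason, call = sys.call(-1))
  ))
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == floor(x)
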