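# Built-in condition keywords planted into synthetic sample descriptions so the
# semantic-analysis path is testable end to end.
condition_keywords <- c("root", "leaf", "seed", "flower", "stress", "light",
                        "cold", "drought", "salt", "heat")

#' Simulate an expression compendium with planted condition-specific modules
#'
#' Latent-factor model for condition-specific co-expression. Samples are split
#' evenly across `n_conditions`. Every gene gets a baseline `mu_g` (drawn once,
#' N(8, 2) on the log2 scale typical of summarized microarray data). For a
#' planted module gene g and a sample s belonging to the module's condition,
#' `x_gs = mu_g + b * z_s + eps` with `z_s` a per-sample standard-normal latent
#' factor shared by all module genes in that sample and `eps ~ N(0, sigma^2)`;
#' all other entries are `mu_g + eps`. Within a module and its condition the
#' expected Pearson correlation is exactly `b^2 / (b^2 + sigma^2)`; across
#' mixed conditions it dilutes, which is the phenomenon pre-clustering
#' addresses.
#'
#' Sample descriptions embed one condition keyword (e.g. "root", "leaf") so
#' keyword assignment and enrichment-ratio analyses can be tested.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param n_conditions number of latent conditions; `n_samples` must be at
#'   least `2 * n_conditions`.
#' @param modules_per_condition,module_size planted co-expression modules per
#'   condition and genes per module; `modules_per_condition * module_size`
#'   must not exceed `n_genes`. Modules within a condition are disjoint, and
#'   across conditions too when `n_genes` has room.
#' @param b latent factor loading (default 1.2).
#' @param sigma noise standard deviation (default 1).
#' @param condition_sd standard deviation `tau` of the per-(gene, condition)
#'   baseline signature (default 0.5). Every gene receives a constant offset
#'   `eta_gc ~ N(0, tau^2)` in each condition — the tissue/treatment-specific
#'   expression level that lets samples of a condition cluster together.
#'   Being constant within a condition it does not change within-cluster
#'   correlations; across mixed conditions it induces only weak correlations
#'   (attenuated by `tau^2 / (tau^2 + sigma^2)`), well below a hard
#'   significance threshold at the default value.
#' @param seed integer seed; the generator is a pure function of its
#'   parameters and seed.
#' @return List with `expression` (an [expression_matrix()]), `metadata`
#'   (sample_id, series_id, description) and `truth` (condition per sample,
#'   planted module gene sets per condition, keyword per condition, `b`,
#'   `sigma`, and the expected within-module correlation).
#' @export
#' @examples
#' sim <- simulate_compendium(n_genes = 60, n_samples = 20, n_conditions = 2,
#'                            modules_per_condition = 1, module_size = 10,
#'                            b = 3, sigma = 1, seed = 1)
#' sim$truth$expected_r  # 0.9
simulate_compendium <- function(n_genes = 600, n_samples = 150,
                                n_conditions = 3, modules_per_condition = 3,
                                module_size = 40, b = 1.2, sigma = 1,
                                condition_sd = 0.5, seed = 1L) {
  stopifnot(is_count(n_genes), is_count(n_samples), is_count(n_conditions),
            is_count(modules_per_condition), is_count(module_size),
            b >= 0, sigma > 0, condition_sd >= 0)
  if (modules_per_condition * module_size > n_genes) {
    stop("modules_per_condition * module_size exceeds n_genes")
  }
  if (n_samples < 2 * n_conditions) {
    stop("need at least 2 samples per condition")
  }
  set.seed(seed)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  condition <- rep(seq_len(n_conditions), length.out = n_samples)
  condition <- sort(condition)  # contiguous, even split (sizes differ by <=1)
  mu <- rnorm(n_genes, mean = 8, sd = 2)
  X <- matrix(rnorm(n_genes * n_samples, sd = sigma), n_genes, n_samples) + mu
  eta <- matrix(rnorm(n_genes * n_conditions, sd = condition_sd),
                n_genes, n_conditions)
  X <- X + eta[, condition]

  # allocate module genes: disjoint across all conditions when space allows,
  # otherwise each condition reuses the leading block (still disjoint within)
  per_cond <- modules_per_condition * module_size
  distinct_all <- n_conditions * per_cond <= n_genes
  planted <- vector("list", n_conditions)
  z <- matrix(rnorm(n_samples * modules_per_condition),
              n_samples, modules_per_condition)
  for (cc in seq_len(n_conditions)) {
    offset <- if (distinct_all) (cc - 1L) * per_cond else 0L
    cols <- which(condition == cc)
    mods <- vector("list", modules_per_condition)
    for (j in seq_len(modules_per_condition)) {
      rows <- offset + (j - 1L) * module_size + seq_len(module_size)
      mods[[j]] <- gene_ids[rows]
      if (b > 0) {
        X[rows, cols] <- X[rows, cols] +
          rep(b * z[cols, j], each = module_size)
      }
    }
    names(mods) <- sprintf("C%d_M%d", cc, seq_len(modules_per_condition))
    planted[[cc]] <- mods
  }
  dimnames(X) <- list(gene_ids, sample_ids)

  keywords <- rep_len(condition_keywords, n_conditions)
  series <- sprintf("SER%d_%d", condition,
                    (unlist(lapply(table(condition), seq_len)) - 1L) %/% 5L + 1L)
  replicate_no <- unlist(lapply(table(condition), seq_len))
  metadata <- data.frame(
    sample_id = sample_ids,
    series_id = series,
    description = sprintf(
      "transcriptome profiling of arabidopsis %s tissue replicate %d",
      keywords[condition], replicate_no),
    stringsAsFactors = FALSE
  )
  list(
    expression = expression_matrix(X, gene_ids, sample_ids),
    metadata = metadata,
    truth = list(
      condition_of_sample = stats::setNames(condition, sample_ids),
      planted_modules = planted,
      condition_keyword = keywords,
      b = b, sigma = sigma, condition_sd = condition_sd,
      expected_r = b^2 / (b^2 + sigma^2)
    )
  )
}

#' Draw i.i.d. degrees from a discrete power law
#'
#' Inverse-CDF sampling from `P(k) proportional to k^(-gamma)` on the
#' truncated support `k = xmin, ..., k_max` (default truncation 1e6; the tail
#' mass beyond it is negligible for any `gamma > 1` of practical interest).
#'
#' @param n number of draws.
#' @param gamma exponent, must be > 1 (the law is non-normalizable otherwise).
#' @param xmin smallest degree (>= 1).
#' @param seed integer seed.
#' @param k_max support truncation point.
#' @return Integer-valued numeric vector of length `n`.
#' @export
simulate_power_law_degrees <- function(n, gamma, xmin = 1L, seed = 1L,
                                       k_max = 1e6) {
  stopifnot(is_count(n), is_count(xmin), xmin >= 1)
  if (gamma <= 1) stop("gamma must be > 1 (non-normalizable otherwise)")
  set.seed(seed)
  support <- seq(xmin, k_max)
  cdf <- cumsum(support^(-gamma))
  cdf <- cdf / cdf[length(cdf)]
  support[findInterval(runif(n), cdf, left.open = TRUE) + 1L]
}

#' Simulate an undirected planted-partition graph
#'
#' Simple graph on `sum(block_sizes)` nodes; each within-block pair is an edge
#' with probability `p_in`, each between-block pair with probability `p_out`.
#'
#' @param block_sizes integer vector of block sizes.
#' @param p_in,p_out edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed integer seed.
#' @return List with `edges` (data frame `a`, `b`) and `blocks` (named block
#'   index per node).
#' @export
simulate_planted_partition_graph <- function(block_sizes, p_in, p_out,
                                             seed = 1L) {
  stopifnot(all(block_sizes >= 1))
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  set.seed(seed)
  n <- sum(block_sizes)
  nodes <- sprintf("N%04d", seq_len(n))
  block <- rep(seq_along(block_sizes), block_sizes)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- block[idx[, 1]] == block[idx[, 2]]
  p <- ifelse(same, p_in, p_out)
  keep <- runif(nrow(idx)) < p
  list(
    edges = data.frame(a = nodes[idx[keep, 1]], b = nodes[idx[keep, 2]],
                       stringsAsFactors = FALSE),
    blocks = stats::setNames(block, nodes)
  )
}
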