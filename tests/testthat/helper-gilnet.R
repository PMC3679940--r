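# shared fixture builders (everything is generated in code; no data files)

# block-structured expression matrix: n_blocks planted latent-factor modules of
# block_size genes on a background of independent noise genes
planted_block_matrix <- function(seed, n_genes = 500, n_blocks = 5,
                                 block_size = 20, n_samples = 50,
                                 b = 3, sigma = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n_genes * n_samples, sd = sigma), n_genes, n_samples) +
    rnorm(n_genes, 8, 2)
  truth <- rep(0L, n_genes)
  for (k in seq_len(n_blocks)) {
    rows <- (k - 1) * block_size + seq_len(block_size)
    truth[rows] <- k
    X[rows, ] <- X[rows, ] + b * rep(rnorm(n_samples), each = block_size)
  }
  dimnames(X) <- list(sprintf("G%03d", seq_len(n_genes)),
                      sprintf("S%03d", seq_len(n_samples)))
  list(X = expression_matrix(X), truth = truth)
}

make_net <- function(a, b, r = rep(1, length(a)), threshold = NA_real_) {
  coexpression_network(data.frame(a = a, b = b, r = r,
                                  stringsAsFactors = FALSE),
                       threshold = threshold)
}

triangle_net <- function() make_net(c("A", "A", "B"), c("B", "C", "C"))

# planted-partition graph as a unit-weight network
ppg_net <- function(block_sizes, p_in, p_out, seed) {
  g <- simulate_planted_partition_graph(block_sizes, p_in, p_out, seed)
  list(net = make_net(g$edges$a, g$edges$b), blocks = g$blocks)
}

# random simple graph as a network (for oracle-equivalence tests)
random_net <- function(seed, n = 30, p = 0.2) {
  set.seed(seed)
  nodes <- sprintf("V%02d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p
  make_net(nodes[idx[keep, 1]], nodes[idx[keep, 2]],
           r = runif(sum(keep), 0.5, 1))
}

expect_partition <- function(modules, nodes) {
  all_genes <- unlist(modules, use.names = FALSE)
  expect_equal(sort(all_genes), sort(nodes))
}
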