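test_that("MCL clusters basic graphs correctly and returns a partition", {
  # two disjoint triangles: exactly 2 clusters of 3
  net <- make_net(c("a", "a", "b", "x", "x", "y"),
                  c("b", "c", "c", "y", "z", "z"))
  ms <- mcl(net)
  expect_equal(ms$method, "mcl")
  expect_length(ms$modules, 2)
  expect_equal(sort(unname(lengths(ms$modules))), c(3L, 3L))
  expect_partition(ms$modules, net$nodes)

  # single edge: one cluster of 2
  ms1 <- mcl(make_net("a", "b"))
  expect_length(ms1$modules, 1)
  expect_equal(ms1$modules[[1]], c("a", "b"))

  expect_error(mcl(coexpression_network(
    data.frame(a = character(), b = character(), r = numeric()))),
    "non-empty")
})

test_that("MCL recovers planted partitions and never merges components", {
  g <- ppg_net(rep(30, 5), 0.9, 0.02, seed = 17)
  ms <- mcl(g$net, inflation = 2)
  memb <- stats::setNames(rep(names(ms$modules), lengths(ms$modules)),
                          unlist(ms$modules, use.names = FALSE))
  ari <- adjusted_rand_index(memb[names(g$blocks)], g$blocks)
  expect_gte(ari, 0.9)
  expect_partition(ms$modules, g$net$nodes)

  # disconnected components stay separate (igraph oracle)
  skip_if_not_installed("igraph")
  net2 <- random_net(5, n = 24, p = 0.12)
  ig <- igraph::graph_from_data_frame(net2$edges[1:2], directed = FALSE)
  comp <- igraph::components(ig)$membership
  ms2 <- mcl(net2)
  for (mod in ms2$modules) {
    expect_length(unique(comp[mod]), 1)
  }
})

test_that("link communities: triangle density, trees, and overlapping cliques", {
  lc <- link_communities(triangle_net())
  expect_equal(lc$partition_density, 1)
  expect_length(lc$module_set$modules, 1)

  # tree: every cut yields chain communities with m_c = n_c - 1, so D = 0
  tree <- make_net(c("a", "b", "c", "c"), c("b", "c", "d", "e"))
  lt <- link_communities(tree)
  expect_equal(lt$partition_density, 0)

  # two 4-cliques sharing one node: shared node in 2 communities
  cl <- function(nodes) t(combn(nodes, 2))
  p1 <- cl(c("h", "a1", "a2", "a3"))
  p2 <- cl(c("h", "b1", "b2", "b3"))
  both <- rbind(p1, p2)
  net <- make_net(both[, 1], both[, 2])
  lk <- link_communities(net)
  in_mods <- vapply(lk$module_set$modules, function(m) "h" %in% m, logical(1))
  expect_gte(sum(in_mods), 2)

  # brute force over every dendrogram cut: the reported D is the maximum
  # and the reported D equals an independent recomputation
  recompute <- function(groups, edges) {
    M <- nrow(edges)
    tot <- 0
    for (idx in groups) {
      m_c <- length(idx)
      n_c <- length(unique(c(edges$a[idx], edges$b[idx])))
      if (n_c > 2) tot <- tot + m_c * (m_c - (n_c - 1)) /
          ((n_c - 2) * (n_c - 1))
    }
    2 * tot / M
  }
  expect_equal(recompute(lk$module_set$edge_modules, net$edges),
               lk$partition_density, tolerance = 1e-12)
  # both cliques perfectly circumscribed: D = 1 is attainable, so D* = 1
  expect_equal(lk$partition_density, 1, tolerance = 1e-12)

  # edge communities partition the edge set
  expect_equal(sort(unlist(lk$module_set$edge_modules, use.names = FALSE)),
               seq_len(nrow(net$edges)))
})

test_that("module size statistics match the stated summaries", {
  ms <- structure(list(method = "mcl",
                       modules = list(M1 = c("a", "b"),
                                      M2 = c("c", "d", "e"))),
                  class = "ModuleSet")
  st <- module_size_stats(ms, n_nodes = 5)
  expect_equal(st$count, 2L)
  expect_equal(st$median_size, 2.5)
  expect_equal(st$min_size, 2L)
  expect_equal(st$max_size, 3L)
  expect_equal(st$coverage, 1)  # a partition always covers the node set

  empty <- structure(list(method = "mcl", modules = list()),
                     class = "ModuleSet")
  st0 <- module_size_stats(empty)
  expect_equal(st0$count, 0L)
  expect_true(is.na(st0$median_size))
})
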