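test_that("published summary arithmetic recomputes from its integer inputs", {
  expect_equal(coverage_percent(19588, 20677), 94.7)
  expect_equal(coverage_percent(3297, 20677), 15.9)
  expect_equal(mean_cluster_size(7105, 90), 78.9)
  expect_equal(mean_cluster_size(7105, 30), 236.8)
  expect_equal(extrapolate_interactome(558022, 19588, 20677), 589045)
  expect_equal(extrapolate_interactome(100, 50, 100), 200)
  expect_equal(extrapolate_interactome(7, 10, 10), 7)  # identity case

  ov <- edge_overlap(paste0("e", 1:237), paste0("e", 1:11374))
  expect_equal(ov$count, 237L)
  expect_equal(ov$percent_of_b, 2.1)
  expect_equal(edge_overlap("a|b", "c|d")$percent_of_b, 0)
  expect_equal(edge_overlap(c("a|b", "c|d"), c("a|b", "c|d"))$percent_of_b,
               100)
  expect_true(is.na(edge_overlap("a|b", character(0))$percent_of_b))
})

test_that("capture unions canonicalize edges and count unique nodes", {
  n1 <- make_net(c("a", "b"), c("b", "c"), c(0.9, 0.8))
  n2 <- make_net(c("c", "b"), c("d", "a"), c(0.7, 0.9))  # (b,a) == (a,b)
  cp <- structure(list(K = 2L, seed = 1L,
                       partition = NULL,
                       gils = list(
                         GIL001 = list(status = "built", network = n1,
                                       sample_ids = c("s1", "s2")),
                         GIL002 = list(status = "built", network = n2,
                                       sample_ids = c("s3", "s4"))),
                       config = list()),
                  class = "GILCompendium")
  cap <- compendium_capture(cp)
  expect_equal(cap$nodes, c("a", "b", "c", "d"))
  expect_length(cap$edges, 3)  # a|b counted once across layers
  curve <- capture_curve(list(cp))
  expect_equal(curve$unique_nodes, 4L)
  expect_equal(curve$unique_edges, 3L)
  expect_equal(curve$success_rate, 1)
})

test_that("keyword assignment, enrichment ratio and layer ordering", {
  kws <- assign_keywords(list(g1 = c("root root leaf", "the root sample")),
                         stoplist = c("the", "sample"), top_n = 2)
  expect_equal(kws$g1[1], "root")
  expect_false("the" %in% kws$g1)
  all_stop <- assign_keywords(list(g = "root leaf"),
                              stoplist = c("root", "leaf"))
  expect_length(all_stop$g, 0)

  # identical per-layer match counts and group sizes: ratio exactly 1
  kw <- list(a = "root", b = "root", c = "leaf", d = "leaf")
  desc <- list(a = c("root growth", "x"), b = "root hair",
               c = c("root cap", "y"), d = "root meristem")
  expect_equal(keyword_enrichment_ratio(kw, desc, "root", "root"), 1)
  # zero matches outside the keyword group: infinite ratio
  desc2 <- list(a = "root growth", b = "root hair", c = "shoot", d = "flower")
  expect_equal(keyword_enrichment_ratio(kw, desc2, "root", "root"), Inf)
  expect_error(keyword_enrichment_ratio(kw, desc, "auxin", "auxin"),
               "non-empty")

  # ordering: identical layers adjacent; similarity symmetric with
  # own coverage on the diagonal
  sets <- list(A = paste0("g", 1:30), B = paste0("g", 1:30),
               C = paste0("h", 1:30))
  ord <- order_gils(sets)
  pos <- match(c("A", "B"), ord$order)
  expect_equal(abs(diff(pos)), 1)
  expect_true(isSymmetric(ord$similarity))
  expect_equal(unname(diag(ord$similarity)), c(30, 30, 30))

  # permutation test: planted adjacency of shared keywords is non-random
  kws2 <- stats::setNames(
    as.list(c(rep("root", 6), rep("leaf", 6))), paste0("L", 1:12))
  ordered <- paste0("L", 1:12)  # keyword groups contiguous
  tst <- keyword_order_test(ordered, kws2, n_perm = 500, seed = 4)
  expect_lt(tst$p_value, 0.05)
  # under a null of unique keywords, nothing is ever shared
  kws3 <- stats::setNames(as.list(paste0("w", 1:12)), paste0("L", 1:12))
  tst3 <- keyword_order_test(ordered, kws3, n_perm = 100, seed = 4)
  expect_equal(tst3$statistic, 0)
})

test_that("a small compendium builds deterministically and K=1 is the global path", {
  sim <- simulate_compendium(n_genes = 300, n_samples = 60, n_conditions = 2,
                             modules_per_condition = 3, module_size = 40,
                             b = 3, sigma = 1, seed = 31)
  cfg <- list(modules = "mcl")
  cp_a <- build_compendium(sim$expression, K = 2, seed = 31, config = cfg)
  cp_b <- build_compendium(sim$expression, K = 2, seed = 31, config = cfg)
  expect_identical(compendium_capture(cp_a), compendium_capture(cp_b))
  expect_s3_class(cp_a, "GILCompendium")

  # K = 1: single layer from all samples
  cp1 <- build_compendium(sim$expression, K = 1, seed = 31, config = cfg)
  expect_length(cp1$gils, 1)
  expect_equal(length(cp1$partition$assignment), 60L)

  summ <- compendium_summary(cp_a, n_measurable = 300,
                             metadata = sim$metadata)
  expect_equal(summ$K, 2L)
  expect_equal(summ$mean_arrays_per_cluster, 30)
  expect_equal(summ$coverage_percent,
               round(100 * summ$unique_nodes / 300, 1))
  expect_true(summ$n_built >= 1)

  # per-layer keyword lists surface the planted condition keywords
  kw <- compendium_keywords(cp_a, sim$metadata,
                            stoplist = c("transcriptome", "profiling",
                                         "tissue", "replicate",
                                         "arabidopsis"))
  built_ids <- names(kw)
  expect_true(all(vapply(kw, function(k) k[1] %in% c("root", "leaf"),
                         logical(1))))
})
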