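test_that("degree statistics reproduce printed network summaries", {
  tri <- triangle_net()
  st <- degree_stats(tri)
  expect_equal(st$n_nodes, 3L)
  expect_equal(st$n_edges, 3L)
  expect_equal(st$avg_degree, 2)

  # published arithmetic: global network and one layer row
  expect_equal(average_degree(3297, 129134, digits = 0), 78)
  expect_equal(average_degree(1921, 7807), 8.13)

  expect_error(degree_stats(coexpression_network(
    data.frame(a = character(), b = character(), r = numeric()))),
    "non-empty")
})

test_that("power-law MLE matches closed form and a numeric maximizer", {
  x <- c(1, 2, 4, 8)
  g_hat <- fit_power_law(x, xmin = 1, min_tail = 4)
  expect_equal(g_hat, 1 + 4 / sum(log(x / 0.5)), tolerance = 1e-12)
  expect_equal(g_hat, 1.577, tolerance = 1e-3)

  # independent oracle: numeric maximization of the continuous log-likelihood
  x2 <- simulate_power_law_degrees(2000, gamma = 2.2, xmin = 2, seed = 6)
  loglik <- function(g) {
    length(x2) * log(g - 1) - length(x2) * log(2 - 0.5) -
      g * sum(log(x2 / (2 - 0.5)))
  }
  opt <- stats::optimize(loglik, c(1.01, 6), maximum = TRUE)$maximum
  expect_equal(fit_power_law(x2, xmin = 2), opt, tolerance = 1e-4)

  # tail definition: values below xmin never change the estimate
  expect_equal(fit_power_law(c(x2, rep(1, 50)), xmin = 2),
               fit_power_law(x2, xmin = 2))

  expect_error(fit_power_law(rep(3, 20), xmin = 3), "undefined")
  expect_error(fit_power_law(1:5, xmin = 1), "at least 10")
})

test_that("clustering coefficient matches brute-force triangle counting", {
  expect_equal(clustering_coefficient(triangle_net()), 1)
  star <- make_net(rep("hub", 4), paste0("leaf", 1:4))
  expect_equal(clustering_coefficient(star), 0)

  brute <- function(net) {
    nodes <- net$nodes
    adj <- lapply(stats::setNames(nodes, nodes), function(v) {
      c(net$edges$b[net$edges$a == v], net$edges$a[net$edges$b == v])
    })
    mean(vapply(nodes, function(v) {
      nb <- adj[[v]]
      d <- length(nb)
      if (d < 2) return(0)
      tri <- 0
      for (i in seq_len(d - 1)) {
        for (j in seq((i + 1), d)) {
          if (nb[j] %in% adj[[nb[i]]]) tri <- tri + 1
        }
      }
      2 * tri / (d * (d - 1))
    }, numeric(1)))
  }
  for (seed in 1:3) {
    net <- random_net(seed, n = 30, p = 0.15)
    expect_equal(clustering_coefficient(net), brute(net), tolerance = 1e-12)
  }
})

test_that("Fisher enrichment equals the exhaustive example and edge cases", {
  bg <- paste0("g", 1:20)
  # N=20, K=4, n=5, k=3: (C(4,3)C(16,2) + C(4,4)C(16,1)) / C(20,5)
  p <- fisher_enrichment(paste0("g", 1:5), paste0("g", c(1:3, 6)), bg)
  expect_equal(p, 496 / 15504, tolerance = 1e-12)

  # k = 0: P(X >= 0) is the certain event
  expect_equal(fisher_enrichment(paste0("g", 1:5), paste0("g", 15:18), bg), 1)
  # module = term = background: certain overlap, p = 1
  expect_equal(fisher_enrichment(bg, bg, bg), 1)
  expect_warning(p0 <- fisher_enrichment(character(0), bg, bg), "empty")
  expect_equal(p0, 1)

  expect_equal(bonferroni(0.001, 10), 0.01)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(0.123, 1), 0.123)
})

test_that("module enrichment table respects family size and significance", {
  bg <- paste0("g", 1:100)
  ms <- structure(list(method = "mcl",
                       modules = list(M1 = paste0("g", 1:10),
                                      M2 = paste0("g", 50:51))),
                  class = "ModuleSet")
  ann <- annotation_set("GO", list(T1 = paste0("g", 1:10),
                                   T2 = paste0("g", 90:99)))
  tab <- enrich_modules(ms, ann, bg)
  # M2 skipped (below min size); two terms tested for M1
  expect_equal(unique(tab$module_id), "M1")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$p_adj, pmin(1, tab$p * 2))
  expect_true(tab$significant[tab$term_id == "T1"])
  expect_false(tab$significant[tab$term_id == "T2"])

  # enrichment count is monotone non-increasing in the cutoff
  counts <- vapply(c(0.1, 0.01, 0.001, 1e-6),
                   function(a) sum(tab$p_adj < a), numeric(1))
  expect_true(all(diff(counts) <= 0))

  # global family mode multiplies by modules x terms
  tab_g <- enrich_modules(ms, ann, bg, family = "global")
  expect_equal(tab_g$p_adj, pmin(1, tab_g$p * 2))
})
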