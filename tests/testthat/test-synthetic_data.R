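test_that("compendium generator plants the advertised correlation structure", {
  # b = 3, sigma = 1: expected within-module, within-condition r = 0.9
  sim <- simulate_compendium(n_genes = 80, n_samples = 100, n_conditions = 2,
                             modules_per_condition = 1, module_size = 10,
                             b = 3, sigma = 1, seed = 11)
  expect_equal(sim$truth$expected_r, 0.9)
  cond <- sim$truth$condition_of_sample
  mod <- sim$truth$planted_modules[[1]][[1]]
  cols <- names(cond)[cond == 1]  # 50 samples in condition 1
  r <- cor(t(unclass(sim$expression)[mod, cols]))
  expect_equal(mean(r[upper.tri(r)]), 0.9, tolerance = 0.05)

  # b = 0: no signal; mean within-module r indistinguishable from background
  sim0 <- simulate_compendium(n_genes = 80, n_samples = 100, n_conditions = 2,
                              modules_per_condition = 1, module_size = 10,
                              b = 0, sigma = 1, condition_sd = 0,
                              seed = 12)
  cond0 <- sim0$truth$condition_of_sample
  mod0 <- sim0$truth$planted_modules[[1]][[1]]
  cols0 <- names(cond0)[cond0 == 1]
  r0 <- cor(t(unclass(sim0$expression)[mod0, cols0]))
  m <- length(cols0)
  expect_lt(abs(mean(r0[upper.tri(r0)])), 3 / sqrt(m))

  # determinism and metadata keywords
  sim_a <- simulate_compendium(n_genes = 40, n_samples = 12, n_conditions = 3,
                               modules_per_condition = 1, module_size = 5,
                               seed = 5)
  sim_b <- simulate_compendium(n_genes = 40, n_samples = 12, n_conditions = 3,
                               modules_per_condition = 1, module_size = 5,
                               seed = 5)
  expect_identical(unclass(sim_a$expression), unclass(sim_b$expression))
  expect_true(all(grepl("root|leaf|seed", sim_a$metadata$description)))

  # planted modules within a condition are disjoint
  for (mods in sim_a$truth$planted_modules) {
    genes <- unlist(mods)
    expect_equal(anyDuplicated(genes), 0L)
  }

  expect_error(simulate_compendium(n_genes = 10, n_samples = 10,
                                   n_conditions = 2,
                                   modules_per_condition = 3,
                                   module_size = 5),
               "exceeds n_genes")
  expect_error(simulate_compendium(n_genes = 10, n_samples = 3,
                                   n_conditions = 2,
                                   modules_per_condition = 1,
                                   module_size = 5),
               "2 samples per condition")
})

test_that("power-law degree generator respects support and is reproducible", {
  d <- simulate_power_law_degrees(2000, gamma = 2.5, xmin = 5, seed = 3)
  expect_true(all(d >= 5))
  expect_identical(d, simulate_power_law_degrees(2000, gamma = 2.5, xmin = 5,
                                                 seed = 3))
  expect_error(simulate_power_law_degrees(10, gamma = 1), "gamma")

  # round-trip through the MLE at moderate n (xmin in the estimator's
  # validity regime; see the methods vignette)
  d2 <- simulate_power_law_degrees(1e4, gamma = 2.5, xmin = 5, seed = 4)
  expect_equal(fit_power_law(d2, xmin = 5), 2.5, tolerance = 0.1)
})

test_that("planted-partition graphs match their binomial edge moments", {
  # p_in = 1, p_out = 0, blocks [3,3]: two disjoint triangles
  g <- simulate_planted_partition_graph(c(3, 3), 1, 1e-12, seed = 1)
  expect_equal(nrow(g$edges), 6L)
  cross <- g$blocks[g$edges$a] != g$blocks[g$edges$b]
  expect_false(any(cross))

  # expected edge count within 4 sd of the binomial moments
  sizes <- rep(30, 5)
  p_in <- 0.9
  p_out <- 0.02
  g2 <- simulate_planted_partition_graph(sizes, p_in, p_out, seed = 2)
  n_within <- sum(choose(sizes, 2))
  n_between <- (sum(sizes)^2 - sum(sizes^2)) / 2
  mu <- n_within * p_in + n_between * p_out
  sdv <- sqrt(n_within * p_in * (1 - p_in) + n_between * p_out * (1 - p_out))
  expect_lt(abs(nrow(g2$edges) - mu), 4 * sdv)

  expect_error(simulate_planted_partition_graph(c(3, 3), 0.2, 0.5), "p_out")
})
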