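test_that("modularity Q matches closed-form values", {
  W <- clique_graph(2, 3, win = 1, wbridge = 0)
  split2 <- rep(1:2, each = 3)
  expect_equal(modularity_q(W, split2, gamma = 1), 0.5, tolerance = 1e-12)
  # one module at gamma 1 is exactly zero
  expect_equal(modularity_q(W, rep(1, 6), gamma = 1), 0, tolerance = 1e-14)
  # singletons on a loop-free graph are negative
  expect_lt(modularity_q(W, 1:6, gamma = 1), 0)
  # the two-clique split is the enumerated maximum
  expect_equal(max_q_enumeration(W)$Q, 0.5, tolerance = 1e-12)
  Wa <- W; Wa[1, 2] <- 5
  expect_error(modularity_q(Wa, split2), "symmetric")
})

test_that("louvain recovers planted cliques and attains the enumerated optimum", {
  W <- clique_graph(3, 3, win = 1, wbridge = 0.1)   # 9 nodes, 3 cliques
  planted <- rep(1:3, each = 3)
  part <- louvain(W, gamma = 1, seed = 2)
  expect_equal(compare_partitions(part, planted), 1)
  expect_equal(part$Q, max_q_enumeration(W)$Q, tolerance = 1e-12)

  # warm start at the optimum is a fixed point
  warm <- louvain(W, gamma = 1, init_labels = planted, seed = 5)
  expect_equal(compare_partitions(warm, planted), 1)
  # warm and cold starts meet at the same Q on planted cliques
  expect_equal(warm$Q, part$Q, tolerance = 1e-12)
  # Q never falls below the Q of the init
  bad_init <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)
  from_bad <- louvain(W, gamma = 1, init_labels = bad_init, seed = 3)
  expect_gte(from_bad$Q, modularity_q(W, bad_init, 1))
  expect_error(louvain(W, init_labels = 1:5), "length mismatch")
})

test_that("gamma controls resolution without decreasing module counts", {
  W <- clique_graph(2, 4, win = 1, wbridge = 0.9)
  counts <- sapply(c(0.5, 1, 1.5, 2, 2.5), function(g) {
    max(louvain(W, gamma = g, seed = 4)$assignment)
  })
  expect_true(all(diff(counts) >= 0))
  expect_lt(counts[1], counts[length(counts)])
})

test_that("louvain agrees with igraph's implementation on fixture graphs", {
  for (W in small_graph_suite()[c("two_triangles", "random7")]) {
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    set.seed(1)
    ig <- igraph::cluster_louvain(g, resolution = 1)
    q_ig <- modularity_q(W, igraph::membership(ig), gamma = 1)
    q_ours <- louvain(W, gamma = 1, seed = 1)$Q
    expect_gte(q_ours, q_ig - 1e-9)
  }
})

test_that("map-equation codelength matches direct evaluation", {
  W <- clique_graph(2, 4, win = 1, wbridge = 0)    # disconnected cliques
  one <- rep(1L, 8)
  two <- rep(1:2, each = 4)
  expect_warning(L1 <- map_equation_codelength(W, one), "disconnected")
  expect_warning(L2 <- map_equation_codelength(W, two), "disconnected")
  # single module: entropy of the stationary visit distribution
  p <- rowSums(W) / sum(W)
  expect_equal(L1, -sum(p * log2(p)), tolerance = 1e-12)
  expect_lt(L2, L1)
  # direct-formula oracle agreement
  expect_equal(L2, codelength_direct(W, two), tolerance = 1e-12)
  Wb <- clique_graph(2, 4, win = 1, wbridge = 0.3)
  expect_equal(map_equation_codelength(Wb, two),
               codelength_direct(Wb, two), tolerance = 1e-12)
  # rescaling all weights leaves the codelength unchanged
  expect_equal(map_equation_codelength(2 * Wb, two),
               map_equation_codelength(Wb, two), tolerance = 1e-12)
})

test_that("infomap recovers planted cliques deterministically", {
  W <- clique_graph(3, 4, win = 1, wbridge = 0.1)
  planted <- rep(1:3, each = 4)
  p1 <- infomap_partition(W, seed = 3)
  p2 <- infomap_partition(W, seed = 3)
  expect_identical(p1$assignment, p2$assignment)
  expect_equal(compare_partitions(p1, planted), 1)
  # output codelength beats the degenerate partitions
  expect_lte(p1$L, map_equation_codelength(W, rep(1L, 12)) + 1e-12)
  expect_lte(p1$L, map_equation_codelength(W, 1:12) + 1e-12)
})

test_that("adjusted Rand index has its closed-form landmarks", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(compare_partitions(a, a), 1)
  expect_equal(compare_partitions(a, c(2, 2, 3, 3, 1, 1)), 1)  # relabelled
  expect_equal(compare_partitions(1:6, rep(1, 6)), 0)          # degenerate pair
  b <- c(1, 2, 1, 2, 3, 3)
  expect_equal(compare_partitions(a, b), compare_partitions(b, a))
  expect_error(compare_partitions(a, b[-1]), "different node sets")
})

test_that("negative connectivity edges are thresholded, not propagated", {
  W <- clique_graph(2, 3, win = 1, wbridge = 0)
  W[1, 4] <- W[4, 1] <- -5
  expect_equal(modularity_q(W, rep(1:2, each = 3)), 0.5, tolerance = 1e-12)
  part <- louvain(W, seed = 1)
  expect_equal(compare_partitions(part, rep(1:2, each = 3)), 1)
})
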