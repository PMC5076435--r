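test_that("two-node and complete graphs give the closed-form metrics", {
  w <- matrix(c(0, 0.5, 0.5, 0), 2)
  g <- network_graph(w)
  expect_equal(unname(node_degree(g)), c(1L, 1L))
  expect_equal(unname(node_strength(g)), c(0.5, 0.5))
  expect_equal(unname(nodal_path_length(g)), c(2, 2))  # 1 / 0.5
  expect_equal(global_efficiency(g), 0.5)
  # complete unit-weight graph: efficiency exactly 1
  wc <- matrix(1, 5, 5); diag(wc) <- 0
  expect_equal(global_efficiency(network_graph(wc)), 1)
})

test_that("indirect routes beat weak direct edges in the distance metric", {
  # direct edge 1-3 weight 0.1 (length 10); route via 2 has length 1 + 1
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  w[1, 3] <- w[3, 1] <- 0.1
  g <- network_graph(w)
  expect_equal(unname(nodal_path_length(g)), c(1.5, 1, 1.5))
  expect_equal(global_efficiency(g), mean(c(1, 1 / 2, 1, 1 / 2, 1, 1)))
})

test_that("disconnected and isolated nodes are handled per definition", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 2
  g <- network_graph(w)
  pl <- nodal_path_length(g)
  expect_equal(unname(pl[1:2]), c(0.5, 0.5))
  expect_true(all(is.na(pl[3:4])))
  expect_equal(global_efficiency(g), (2 + 2) / (4 * 3))
  empty <- network_graph(matrix(0, 3, 3))
  expect_equal(global_efficiency(empty), 0)
  expect_true(all(node_degree(empty) == 0))
})

test_that("metrics agree with the exhaustive oracle on random small graphs", {
  for (seed in 1:25) {
    n <- sample(3:6, 1)
    w <- random_weight_matrix(n, p_edge = runif(1, 0.2, 0.9), seed = seed)
    g <- network_graph(w)
    expect_identical(unname(node_degree(g)), as.integer(rowSums(w > 0)))
    expect_equal(unname(node_strength(g)), unname(rowSums(w)),
                 tolerance = 1e-12)
    expect_equal(unname(nodal_path_length(g)),
                 unname(brute_force_path_length(w)), tolerance = 1e-8)
    expect_equal(global_efficiency(g), brute_force_efficiency(w),
                 tolerance = 1e-8)
  }
})

test_that("interhemispheric similarity is 1 for a mirror-symmetric truth", {
  mods <- rep(c(rep("motor", 3), rep("other", 3)), 2)
  gt <- make_modular_precision(12, mods, symmetry = TRUE, seed = 13,
                               within_module_density = 0.6,
                               between_module_density = 0.2)
  atlas <- list(hemisphere = gt$hemisphere, homotopic_pair = gt$homotopic_pair)
  pc <- precision_to_partial_corr(gt$precision)
  expect_equal(interhemispheric_similarity(pc, atlas), 1, tolerance = 1e-10)
  # breaking one within-left edge lowers the similarity below 1
  v <- pc$values
  v[1, 2] <- v[2, 1] <- v[1, 2] + 0.3
  expect_lt(interhemispheric_similarity(connectivity_matrix(v, "pFC"), atlas), 1)
  few <- list(hemisphere = c("left", "right"), homotopic_pair = c(2L, 1L))
  expect_error(interhemispheric_similarity(pc, few), "at least 3")
})

test_that("subnetwork restriction and binarisation preserve structure", {
  w <- random_weight_matrix(6, seed = 21)
  g <- network_graph(w)
  sub <- subnetwork(g, c("n2", "n4", "n5"))
  expect_identical(sub$node_labels, c("n2", "n4", "n5"))
  expect_equal(sub$weights, w[c(2, 4, 5), c(2, 4, 5)])
  expect_error(subnetwork(g, "nope"), "unknown node labels")
  b <- binarize_network(g)
  expect_true(all(b$weights %in% c(0, 1)))
  expect_identical(unname(node_degree(b)), unname(as.integer(node_strength(b))))
})
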