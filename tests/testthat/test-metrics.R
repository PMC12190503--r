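# Sparsification and graph metrics against brute-force oracles.

test_that("sparsification keeps exactly the ceiling of the top fraction", {
  set.seed(51)
  W <- matrix(0, 5, 5)
  W[upper.tri(W)] <- runif(10)
  W <- W + t(W)
  g <- sparsify_top_fraction(W, 0.10)
  kept <- which(g$weights[upper.tri(g$weights)] > 0)
  expect_length(kept, 1L)
  expect_equal(max(g$weights), max(W))

  W90 <- matrix(0, 90, 90)
  W90[upper.tri(W90)] <- runif(90 * 89 / 2)
  W90 <- W90 + t(W90)
  g90 <- sparsify_top_fraction(W90, 0.10)
  expect_equal(sum(g90$retained[upper.tri(g90$retained)]), 401L)

  full <- sparsify_top_fraction(W, 1.0)
  expect_equal(full$weights, W, ignore_attr = TRUE)
})

test_that("sparsification is idempotent and breaks ties deterministically", {
  set.seed(52)
  W <- matrix(0, 12, 12)
  W[upper.tri(W)] <- runif(66)
  W <- W + t(W)
  g1 <- sparsify_top_fraction(W, 0.2)
  g2 <- sparsify_top_fraction(g1$weights, 0.2)
  expect_equal(g1$weights, g2$weights)
  # all-equal weights: ties resolve to the lexicographically first pairs
  Wt <- matrix(1, 4, 4); diag(Wt) <- 0
  gt <- sparsify_top_fraction(Wt, 1 / 6)
  expect_equal(which(gt$weights[upper.tri(gt$weights)] > 0), 1L)  # pair (1,2)
  expect_error(sparsify_top_fraction(matrix(0, 4, 4), 0.5), "all-zero")
  expect_error(sparsify_top_fraction(W, 0), "fraction")
})

test_that("characteristic path length matches hand calculations", {
  W3 <- matrix(0.5, 3, 3); diag(W3) <- 0
  expect_equal(as.numeric(char_path_length(sparsify_top_fraction(W3, 1))), 2)
  Wp <- matrix(0, 3, 3)
  Wp[1, 2] <- Wp[2, 1] <- 1; Wp[2, 3] <- Wp[3, 2] <- 1
  expect_equal(as.numeric(char_path_length(sparsify_top_fraction(Wp, 1))),
               4 / 3)
})

test_that("path length, clustering and capacity equal brute-force oracles", {
  for (seed in 1:5) {
    g <- rand_graph(15, seed = seed, fraction = 0.3)
    W <- g$weights
    expect_equal(as.numeric(char_path_length(g)), oracle_cpl(W),
                 tolerance = 1e-9)
    cl <- weighted_clustering(g)
    expect_equal(unname(cl$per_node), oracle_clustering(W), tolerance = 1e-9)
    expect_equal(cl$global, mean(oracle_clustering(W)), tolerance = 1e-9)
    expect_equal(unname(communication_capacity(g)),
                 oracle_commcap(W, g$coords), tolerance = 1e-9)
    expect_equal(unname(degree_centrality(g)), unname(rowSums(W > 0) / 14),
                 tolerance = 1e-12)
  }
})

test_that("clustering handles triangles, stars and low-degree nodes", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(unname(weighted_clustering(sparsify_top_fraction(tri, 1))$per_node),
               rep(1, 3))
  tri008 <- tri * 0.008
  cl <- weighted_clustering(sparsify_top_fraction(tri008, 1))
  expect_equal(unname(cl$per_node), rep(0.008, 3), tolerance = 1e-12)
  expect_equal(cl$global, 0.008, tolerance = 1e-12)
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 0.7
  expect_equal(unname(weighted_clustering(sparsify_top_fraction(star, 1))$per_node),
               rep(0, 5))
})

test_that("communication capacity and degree centrality on small graphs", {
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 1
  coords <- rbind(c(0, 0, 0), c(2, 0, 0))
  g <- sparsify_top_fraction(W, 1, coords = coords)
  expect_equal(unname(communication_capacity(g)), c(0.5, 0.5))

  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- 1; W3[2, 3] <- W3[3, 2] <- 1
  coords3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  g3 <- sparsify_top_fraction(W3, 1, coords = coords3)
  expect_equal(unname(degree_centrality(g3)), c(0.5, 1, 0.5))
  expect_equal(unname(communication_capacity(g3))[1], 1)  # isolated ends

  # an isolated node scores 0 on both
  W4 <- matrix(0, 3, 3); W4[1, 2] <- W4[2, 1] <- 1
  g4 <- sparsify_top_fraction(W4, 1 / 3, coords = coords3)
  expect_equal(unname(communication_capacity(g4))[3], 0)
  expect_equal(unname(degree_centrality(g4))[3], 0)

  # duplicate centroids on a retained edge are rejected by name
  gdup <- sparsify_top_fraction(W, 1, coords = rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_error(communication_capacity(gdup), "identical coordinates")
  complete <- matrix(1, 4, 4); diag(complete) <- 0
  expect_equal(unname(degree_centrality(sparsify_top_fraction(complete, 1))),
               rep(1, 4))
})

test_that("per-network summaries follow the complement convention", {
  # two triangles joined by one bridge, all weights 1
  W <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
                 c(3, 4))) {
    W[p[1], p[2]] <- W[p[2], p[1]] <- 1
  }
  g <- sparsify_top_fraction(W, 1)
  md <- data.frame(region = g$region_names,
                   network = rep(c("VIS", "DMN"), each = 3))
  s <- network_summary(g, md)
  # hand enumeration: distances from {1,2,3} to {4,5,6} are
  # node 3 -> (1,2,2), nodes 1,2 -> (2,3,3)
  want <- mean(c(1, 2, 2, 2, 3, 3, 2, 3, 3))
  expect_equal(s$mean_path_between[s$network == "VIS"], want)
  expect_equal(s$mean_path_between[s$network == "DMN"], want)
  # equal-size networks: clustering means average to the global value
  cl <- weighted_clustering(g)
  expect_equal(mean(s$mean_clustering), cl$global, tolerance = 1e-12)
  # a network covering all nodes has no between pairs
  md_all <- data.frame(region = g$region_names, network = "VIS")
  expect_warning(s2 <- network_summary(g, md_all), "covers all")
  expect_true(is.na(s2$mean_path_between))
})

test_that("metrics scale as documented when weights are rescaled", {
  g <- rand_graph(12, seed = 9, fraction = 0.4)
  c_ <- 3.7
  gs <- g
  gs$weights <- g$weights * c_
  expect_equal(as.numeric(char_path_length(gs)),
               as.numeric(char_path_length(g)) / c_, tolerance = 1e-9)
  expect_equal(weighted_clustering(gs)$global,
               weighted_clustering(g)$global * c_, tolerance = 1e-9)
  expect_equal(communication_capacity(gs), communication_capacity(g) * c_,
               tolerance = 1e-9)
  expect_equal(degree_centrality(gs), degree_centrality(g))
  # edge selection itself is scale invariant
  raw <- rand_graph(12, seed = 9, fraction = 1)$weights
  expect_equal(sparsify_top_fraction(raw * c_, 0.4)$retained,
               sparsify_top_fraction(raw, 0.4)$retained)
})

test_that("degenerate graphs raise errors", {
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
  g <- sparsify_top_fraction(W, 1 / 3)
  # node 3 unreachable: excluded pairs are counted, not imputed
  L <- char_path_length(g)
  expect_equal(as.numeric(L), 1)
  expect_equal(attr(L, "n_unreachable"), 4L)
})
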