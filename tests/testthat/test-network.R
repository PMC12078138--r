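random_adjacency <- function(n, p) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

test_that("degree centrality is the incident-edge count", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(unname(degree_centrality(brain_graph(K4))), rep(3L, 4))
  empty <- brain_graph(matrix(0, 5, 5))
  expect_equal(unname(degree_centrality(empty)), rep(0L, 5))
  set.seed(14)
  A <- random_adjacency(20, 0.2)
  g <- brain_graph(A)
  # independent oracle through igraph
  expect_equal(unname(degree_centrality(g)),
               unname(igraph::degree(igraph::graph_from_adjacency_matrix(
                 A, mode = "undirected"))))
})

test_that("weighted degree sums incident weights and reduces to degree", {
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  W <- A * 2.5
  g <- brain_graph(A, weights = W)
  expect_equal(unname(weighted_degree(g)), c(2.5, 2.5, 0))
  set.seed(15)
  A <- random_adjacency(15, 0.3)
  W <- A * matrix(runif(225), 15, 15)
  W <- (W + t(W)) / 2
  g <- brain_graph(A, weights = W)
  expect_equal(unname(weighted_degree(g)), unname(rowSums(g$W)),
               tolerance = 1e-12)
  g1 <- brain_graph(A)
  expect_equal(weighted_degree(g1), degree_centrality(g1) * 1.0,
               ignore_attr = TRUE)
})

test_that("global metrics match hand enumeration and the BFS oracle", {
  # path graph A-B-C
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 1
  m <- global_metrics(brain_graph(P))
  expect_equal(m$density, 2 / 3)
  expect_equal(m$average_path_length, 4 / 3)
  # complete graph
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  mk <- global_metrics(brain_graph(K5))
  expect_equal(mk$density, 1)
  expect_equal(mk$average_path_length, 1)
  # 50 random graphs vs the BFS oracle, exact
  set.seed(16)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    A <- random_adjacency(n, runif(1, 0.05, 0.5))
    m <- global_metrics(brain_graph(A))
    o <- oracle_graph_metrics(A)
    expect_identical(m$average_degree, o$average_degree)
    expect_identical(m$density, o$density)
    expect_equal(m$average_path_length, o$average_path_length,
                 tolerance = 1e-12)
    expect_equal(m$n_disconnected_pairs, o$n_disconnected_pairs)
  }
  # edgeless graph: path length undefined
  expect_true(is.na(global_metrics(brain_graph(matrix(0, 4, 4)))$average_path_length))
})

test_that("handshake lemma and density bounds hold on random graphs", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(4:25, 1)
    g <- brain_graph(random_adjacency(n, runif(1)))
    n_edges <- sum(g$A[upper.tri(g$A)])
    expect_identical(sum(degree_centrality(g)), as.integer(2 * n_edges))
    dens <- global_metrics(g)$density
    expect_gte(dens, 0); expect_lte(dens, 1)
    if (dens == 1) expect_true(all(g$A[upper.tri(g$A)] == 1))
  }
})

test_that("adding an edge never lengthens paths when connectivity is unchanged", {
  set.seed(18)
  tried <- 0
  while (tried < 10) {
    n <- sample(6:15, 1)
    A <- random_adjacency(n, 0.5)
    g <- brain_graph(A)
    if (any(is.infinite(igraph::distances(g$g)))) next  # keep it connected
    miss <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (!nrow(miss)) next
    e <- miss[sample(nrow(miss), 1), ]
    A2 <- A; A2[e[1], e[2]] <- A2[e[2], e[1]] <- 1
    apl1 <- global_metrics(g)$average_path_length
    apl2 <- global_metrics(brain_graph(A2))$average_path_length
    expect_lte(apl2, apl1)
    tried <- tried + 1
  }
})

test_that("largest-component path length ignores satellites", {
  A <- matrix(0, 5, 5)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1  # path of 3 + 2 isolates
  g <- brain_graph(A)
  expect_equal(global_metrics(g, "largest_component")$average_path_length,
               4 / 3)
  expect_equal(global_metrics(g)$n_disconnected_pairs, 2 * (3 * 2 + 1))
})

test_that("macro-region degree lists partition the degree multiset", {
  cfg <- tiny_config()
  atl <- tiny_atlas(cfg)
  set.seed(19)
  n <- nrow(atl$region_table)
  A <- random_adjacency(n, 0.5)
  rownames(A) <- colnames(A) <- as.character(atl$region_table$region_id)
  g <- brain_graph(A)
  md <- macro_region_degrees(g, atl$region_table)
  expect_setequal(unlist(lapply(md, unname)), unname(degree_centrality(g)))
  expect_equal(sum(lengths(md)), n)
  # one macro-region owning all nodes returns the full degree list
  tab1 <- atl$region_table
  tab1$macro_region <- "everything"
  md1 <- macro_region_degrees(g, tab1)
  expect_equal(sort(unname(md1$everything)),
               sort(unname(degree_centrality(g))))
  # unmapped nodes are named in the failure
  tab2 <- atl$region_table[-1, ]
  expect_error(macro_region_degrees(g, tab2), "missing from the region table")
})

test_that("hub subnetworks collect exactly the incident edges", {
  star <- matrix(0, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1
  rownames(star) <- colnames(star) <- letters[1:6]
  g <- brain_graph(star)
  hs <- hub_subnetwork(g, "a")
  expect_equal(hs$n_connections, 5)
  expect_setequal(hs$partners, letters[2:6])
  lonely <- brain_graph(matrix(0, 3, 3), region_ids = c("x", "y", "z"))
  h0 <- hub_subnetwork(lonely, "x")
  expect_equal(h0$n_connections, 0)
  expect_length(h0$partners, 0)
  expect_error(hub_subnetwork(g, character(0)), "nonempty")
  expect_error(hub_subnetwork(g, "nope"), "not in the graph")
})

test_that("edge lists round-trip the suprathreshold structure", {
  Z <- matrix(c(NA, 3, 0.5, 3, NA, -4, 0.5, -4, NA), 3, 3)
  rownames(Z) <- colnames(Z) <- c("r1", "r2", "r3")
  A <- threshold_z(Z, 2.3)
  el <- adjacency_edge_list(A, abs(Z))
  expect_equal(nrow(el), 2)
  expect_setequal(el$weight, c(3, 4))
})
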