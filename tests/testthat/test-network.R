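lab <- function(n) paste0("n", seq_len(n))
named <- function(M) { dimnames(M) <- list(lab(nrow(M)), lab(nrow(M))); M }

# unit-weight graphs used repeatedly
triangle <- named(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
path3 <- named(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))
star4 <- named(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0),
                     c(1, 0, 0, 0), c(1, 0, 0, 0)))
cycle4 <- named(rbind(c(0, 1, 0, 1), c(1, 0, 1, 0),
                      c(0, 1, 0, 1), c(1, 0, 1, 0)))

test_that("threshold_topk keeps exactly the k largest edges", {
  set.seed(10)
  M <- named(random_weighted_graph(4, p = 1))
  W <- threshold_topk(M, 3)
  ut <- which(upper.tri(M), arr.ind = TRUE)
  w <- M[ut]
  kept <- sort(w, decreasing = TRUE)[1:3] # brute-force sort oracle
  expect_equal(sort(W$weights[ut][W$weights[ut] > 0], decreasing = TRUE),
               kept)
  expect_equal(sum(W$weights[ut] > 0), 3)
  expect_identical(W$weights, t(W$weights))
  # full k keeps everything
  Wall <- threshold_topk(M, 6)
  expect_equal(Wall$weights, M)
  # 28-node default: exactly 90 edges survive
  A <- named(random_weighted_graph(28, p = 1))
  W90 <- threshold_topk(A, 90)
  expect_equal(sum(W90$weights[upper.tri(W90$weights)] > 0), 90)
})

test_that("threshold_topk is idempotent and deterministic under ties", {
  set.seed(11)
  M <- named(random_weighted_graph(6, p = 1))
  W1 <- threshold_topk(M, 7)
  W2 <- threshold_topk(W1$weights, 7)
  expect_identical(W1$weights, W2$weights)
  # all weights tied: lexicographic (row, col) pairs win
  Tie <- named(matrix(1, 4, 4)); diag(Tie) <- 0
  Wt <- threshold_topk(Tie, 2)
  expect_equal(Wt$weights[1, 2], 1)
  expect_equal(Wt$weights[1, 3], 1)
  expect_equal(sum(Wt$weights) / 2, 2)
  expect_identical(threshold_topk(Tie, 2)$weights, Wt$weights)
  expect_error(threshold_topk(M, 0), "between")
  expect_error(threshold_topk(M, 16), "between")
})

test_that("nodal clustering matches hand cases and the triple oracle", {
  expect_equal(unname(nodal_clustering(triangle)), rep(1, 3))
  expect_equal(unname(nodal_clustering(path3)), rep(0, 3))
  set.seed(12)
  for (rep in 1:50) {
    W <- random_weighted_graph(6)
    expect_equal(unname(nodal_clustering(W)), oracle_clustering(W),
                 tolerance = 1e-12)
  }
})

test_that("global clustering averages over all nodes including isolates", {
  expect_equal(global_clustering(c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(global_clustering(c(1, 0, 0)), 1 / 3)
  W <- named(matrix(0, 4, 4)) # triangle plus isolated node
  W[1:3, 1:3] <- triangle
  expect_equal(global_clustering(nodal_clustering(W)), 3 / 4)
  set.seed(13)
  G <- random_weighted_graph(6)
  expect_equal(global_clustering(nodal_clustering(G)),
               mean(oracle_clustering(G)), tolerance = 1e-12)
})

test_that("shortest paths use reciprocal-weight lengths", {
  two <- named(matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(shortest_path_lengths(two)[1, 2], 2)
  D <- shortest_path_lengths(path3)
  expect_equal(D[1, 2], 1); expect_equal(D[2, 3], 1)
  expect_equal(D[1, 3], 2)
  set.seed(14)
  for (rep in 1:50) {
    W <- random_weighted_graph(sample(4:7, 1))
    expect_equal(unname(shortest_path_lengths(W)), oracle_distances(W),
                 tolerance = 1e-12)
  }
})

test_that("characteristic path length reports unreachable pairs", {
  expect_equal(char_path_length(shortest_path_lengths(path3))$L, 4 / 3)
  comp <- named(matrix(1, 5, 5)); diag(comp) <- 0
  cp <- char_path_length(shortest_path_lengths(comp))
  expect_equal(cp$L, 1)
  expect_equal(cp$n_unreachable, 0)
  # triangle plus isolated node: 3 reachable pairs, 3 unreachable
  W <- named(matrix(0, 4, 4)); W[1:3, 1:3] <- triangle
  cp2 <- char_path_length(shortest_path_lengths(W))
  expect_equal(cp2$L, 1)
  expect_equal(cp2$n_unreachable, 3)
})

test_that("betweenness matches hand enumeration and the path oracle", {
  expect_equal(unname(node_betweenness(star4)), c(3, 0, 0, 0))
  expect_equal(unname(node_betweenness(cycle4)), rep(0.5, 4))
  set.seed(15)
  for (rep in 1:50) {
    W <- random_weighted_graph(sample(4:7, 1))
    expect_equal(unname(node_betweenness(W)), oracle_betweenness(W),
                 tolerance = 1e-12)
  }
  # complete unit-weight graph: no pair routes through a third node
  comp <- named(matrix(1, 6, 6)); diag(comp) <- 0
  expect_equal(unname(node_betweenness(comp)), rep(0, 6))
})

test_that("surrogates conserve size, degree sequence and weights", {
  set.seed(16)
  M <- named(random_weighted_graph(10, 0.4))
  W <- threshold_topk(M, 12)
  ens <- random_ensemble(W, n_nets = 8, seed = 5)
  orig_w <- sort(W$weights[upper.tri(W$weights)])
  orig_deg <- sort(rowSums(W$weights > 0))
  for (S in ens$surrogates) {
    expect_equal(sum(S[upper.tri(S)] > 0), 12)
    expect_equal(sort(S[upper.tri(S)]), orig_w)
    expect_equal(sort(rowSums(S > 0)), orig_deg)
    expect_identical(S, t(S))
  }
  expect_identical(random_ensemble(W, 8, seed = 5)$c_rand, ens$c_rand)
})

test_that("rewiring destroys lattice clustering", {
  g <- igraph::sample_smallworld(1, 24, 3, 0) # pure ring lattice
  L <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  dimnames(L) <- list(lab(24), lab(24))
  W <- threshold_topk(L, sum(L[upper.tri(L)] > 0))
  ens <- random_ensemble(W, n_nets = 20, seed = 3)
  expect_lt(ens$c_rand, 0.6 * global_clustering(nodal_clustering(W)))
})

test_that("small-worldness is the clustering/path-length double ratio", {
  expect_equal(small_worldness(0.4, 2, 0.2, 2), 2)
  expect_equal(small_worldness(0.3, 1.7, 0.3, 1.7), 1)
  expect_warning(s <- small_worldness(0.4, 2, 0, 2), "undefined")
  expect_true(is.na(s))
})

test_that("metrics respect weight-scaling symmetries", {
  set.seed(17)
  W <- random_weighted_graph(7, 0.6)
  dimnames(W) <- list(lab(7), lab(7))
  for (cs in c(0.2, 5)) {
    expect_equal(nodal_clustering(cs * W), nodal_clustering(W),
                 tolerance = 1e-12)
    expect_equal(node_betweenness(cs * W), node_betweenness(W),
                 tolerance = 1e-12)
    expect_equal(char_path_length(shortest_path_lengths(cs * W))$L,
                 char_path_length(shortest_path_lengths(W))$L / cs,
                 tolerance = 1e-12)
  }
})

test_that("network_metrics bundles all parameters coherently", {
  set.seed(18)
  M <- named(random_weighted_graph(12, 0.8))
  W <- threshold_topk(M, 30)
  nm <- network_metrics(W, n_rand = 5, seed = 2)
  expect_equal(nm$global_clustering, mean(nm$nodal_clustering))
  expect_equal(length(nm$nodal_betweenness), 12)
  expect_true(nm$char_path_length > 0)
  expect_true(is.finite(nm$sigma))
})
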