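# 5-tuple topological features: reputations (dominant eigenvector),
# two-hop sets, shortest-path counts, feature tuples and sequences.

test_that("reputations match closed forms on symmetric graphs", {
  # complete graphs: uniform vector with unit L2 norm
  expect_equal(unname(reputation_vector(edges_k4)), rep(1 / 2, 4), tolerance = 1e-9)
  expect_equal(unname(reputation_vector(edges_k3)), rep(1 / sqrt(3), 3), tolerance = 1e-9)
  # single edge
  expect_equal(unname(reputation_vector(rbind(c("a", "b")))),
               rep(sqrt(2) / 2, 2), tolerance = 1e-9)
  # 3-node path: (1/2, sqrt(2)/2, 1/2)
  k <- reputation_vector(edges_path3)
  expect_equal(k[c("a", "b", "c")], c(a = 0.5, b = sqrt(2) / 2, c = 0.5),
               tolerance = 1e-9)
  expect_error(reputation_vector(matrix(character(0), ncol = 2)), "empty snapshot")
})

test_that("reputation vector agrees with a dense eigendecomposition oracle", {
  set.seed(101)
  for (rep in 1:20) {
    e <- random_graph_edges(sample(3:10, 1))
    nodes <- sort(unique(as.character(e)))
    A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    A[cbind(match(e[, 1], nodes), match(e[, 2], nodes))] <- 1
    A <- A + t(A)    # each unordered pair occurs once, so supports are disjoint
    es <- eigen(A, symmetric = TRUE)
    v <- es$vectors[, 1]
    if (sum(v) < 0) v <- -v
    k <- reputation_vector(e)
    expect_equal(unname(k[nodes]), unname(v), tolerance = 1e-8)
    expect_equal(sum(k^2), 1, tolerance = 1e-9)
    expect_true(all(k >= 0))
  }
})

test_that("reputations are invariant under node relabeling", {
  set.seed(55)
  e <- random_graph_edges(8, 0.4)
  nodes <- sort(unique(as.character(e)))
  perm <- setNames(sample(nodes), nodes)
  e2 <- cbind(perm[e[, 1]], perm[e[, 2]])
  k1 <- reputation_vector(e)
  k2 <- reputation_vector(e2)
  expect_equal(unname(k2[unname(perm[names(k1)])]), unname(k1), tolerance = 1e-8)
})

test_that("two-hop sets exclude the node and its direct neighbors", {
  expect_equal(two_hop_set(edges_path3, "a"), "c")
  expect_equal(two_hop_set(edges_star5, "hub"), character(0))
  expect_equal(two_hop_set(edges_c4, "a"), "c")
  expect_error(two_hop_set(edges_path3, "zz"), "not present")
  # property: disjointness from the 1-hop neighborhood, on random graphs
  set.seed(77)
  for (rep in 1:20) {
    e <- random_graph_edges(sample(4:10, 1))
    nodes <- sort(unique(as.character(e)))
    for (v in nodes) {
      n2 <- two_hop_set(e, v)
      nb <- unique(c(e[e[, 2] == v, 1], e[e[, 1] == v, 2]))
      expect_length(intersect(n2, c(v, nb)), 0)
    }
  }
})

test_that("shortest-path counts equal the common-neighbor count and the walk oracle", {
  expect_equal(shortest_path_count(edges_c4, "c", "a"), 2L)
  expect_equal(shortest_path_count(edges_path3, "c", "a"), 1L)
  # K_{2,3}: the two degree-3 nodes are joined by 3 length-2 paths
  k23 <- rbind(c("u", "m1"), c("u", "m2"), c("u", "m3"),
               c("v", "m1"), c("v", "m2"), c("v", "m3"))
  expect_equal(shortest_path_count(k23, "u", "v"), brute_two_step_paths(k23, "u", "v"))
  expect_equal(shortest_path_count(k23, "u", "v"), 3L)
  expect_error(shortest_path_count(edges_path3, "b", "a"), "not at distance 2")
})

test_that("feature tuples match closed forms on canonical graphs", {
  # triangle: no two-hop structure
  ft <- feature_tuple(edges_k3, "a")
  expect_equal(ft, c(gamma = 1 / sqrt(3), sigma = 2, tau = 2 / sqrt(3),
                     eta = 0, theta = 0), tolerance = 1e-9)
  # path end node: theta = 1/2 * k_c * 1 = 1/4
  fa <- feature_tuple(edges_path3, "a")
  expect_equal(fa, c(gamma = 0.5, sigma = 1, tau = sqrt(2) / 2,
                     eta = 1, theta = 0.25), tolerance = 1e-9)
  # star leaf: eta = 3 other leaves, each with one 2-path through the hub
  fl <- feature_tuple(edges_star5, "leaf1")
  expect_equal(fl, c(gamma = sqrt(2) / 4, sigma = 1, tau = sqrt(2) / 2,
                     eta = 3, theta = 0.5 * 3 * sqrt(2) / 4), tolerance = 1e-9)
  # 5-cycle: k = 1/sqrt(5) everywhere, two two-hop nodes, one path each
  fc <- feature_tuple(edges_c5, "a")
  expect_equal(fc, c(gamma = 1 / sqrt(5), sigma = 2, tau = 2 / sqrt(5),
                     eta = 2, theta = 1 / sqrt(5)), tolerance = 1e-9)
  expect_error(feature_tuple(edges_k3, "zz"), "not present")
})

test_that("batch features agree with the single-node path and tau <= sigma", {
  set.seed(31)
  for (rep in 1:10) {
    e <- random_graph_edges(sample(4:9, 1))
    dn <- dynamic_network(list(e))
    fs <- feature_sequences(dn)
    k <- reputation_vector(e)
    for (v in dn$nodes) {
      expect_equal(fs[[v]][1, ], feature_tuple(e, v, reputation = k),
                   tolerance = 1e-9)
    }
    tab <- feature_table(dn)
    expect_true(all(tab$tau <= tab$sigma + 1e-9))   # each k_x <= 1 under L2
    expect_true(all(tab$theta[tab$eta == 0] == 0))
    expect_true(all(tab$gamma >= 0 & tab$gamma <= 1 + 1e-12))
  }
})

test_that("feature sequences cover exactly the snapshots where the node is present", {
  snaps <- list(rbind(c("a", "b")),
                rbind(c("b", "c")),
                rbind(c("a", "c")),
                rbind(c("b", "c")),
                rbind(c("a", "b"), c("b", "c")))
  dn <- dynamic_network(snaps)
  fa <- feature_sequence(dn, "a")
  expect_equal(attr(fa, "snapshots"), c(0L, 2L, 4L))
  expect_equal(nrow(fa), 3L)
  expect_error(feature_sequence(dn, "zz"), "unknown node")

  # static-replicated network: identical tuples in every snapshot
  dn2 <- dynamic_network(rep(list(edges_k3), 4))
  fb <- feature_sequence(dn2, "b")
  expect_equal(nrow(fb), 4L)
  expect_true(all(apply(fb, 2, function(col) max(col) - min(col)) < 1e-12))
})
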