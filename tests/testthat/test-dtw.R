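# Dynamic time warping: local cost, recurrence, path recovery, Gaussian
# similarity and the cross-network similarity matrix.

test_that("tuple distance is the plain sum of squared differences", {
  expect_equal(tuple_distance(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 0)
  expect_equal(tuple_distance(c(1, 0, 0, 0, 0), rep(0, 5)), 1)
  expect_equal(tuple_distance(c(1, 2, 0, 0, 0), rep(0, 5)), 5)
})

test_that("dtw distance matches the brute-force path enumeration oracle", {
  set.seed(13)
  for (rep in 1:50) {
    p <- random_tuples(sample(1:5, 1))
    q <- random_tuples(sample(1:5, 1))
    res <- dtw(p, q)
    expect_equal(res$distance, brute_dtw(p, q), tolerance = 1e-12)
  }
})

test_that("dtw handles degenerate shapes per the recurrence", {
  p <- random_tuples(1)
  q <- random_tuples(4)
  res <- dtw(p, q)
  # single row: the path is forced through every column
  expect_equal(res$distance, sum(apply(q, 1, function(r) sum((p[1, ] - r)^2))))
  expect_equal(nrow(res$path), 4L)
  # identical sequences: zero distance, diagonal path
  s <- random_tuples(5)
  res2 <- dtw(s, s)
  expect_equal(res2$distance, 0)
  expect_equal(res2$path, cbind(1:5, 1:5))
  expect_error(dtw(s[0, , drop = FALSE], s), "non-empty")
})

test_that("dtw is symmetric and self-distance is zero", {
  set.seed(29)
  for (rep in 1:25) {
    p <- random_tuples(sample(1:5, 1))
    q <- random_tuples(sample(1:5, 1))
    expect_equal(dtw(p, q)$distance, dtw(q, p)$distance, tolerance = 1e-12)
    expect_equal(dtw(p, p)$distance, 0)
  }
})

test_that("returned warping paths satisfy the step and length constraints", {
  set.seed(17)
  for (rep in 1:50) {
    m <- sample(1:5, 1); n <- sample(1:5, 1)
    res <- dtw(random_tuples(m), random_tuples(n))
    w <- res$path
    expect_equal(w[1, ], c(1L, 1L))
    expect_equal(w[nrow(w), ], c(m, n))
    expect_gte(nrow(w), max(m, n))
    expect_lte(nrow(w), m + n - 1L)
    if (nrow(w) > 1) {
      di <- diff(w[, 1]); dj <- diff(w[, 2])
      expect_true(all(di %in% 0:1 & dj %in% 0:1))
      expect_true(all(di + dj > 0))
    }
  }
})

test_that("equal-length dtw is bounded by the diagonal path cost", {
  set.seed(23)
  for (rep in 1:20) {
    m <- sample(2:5, 1)
    p <- random_tuples(m); q <- random_tuples(m)
    diag_cost <- sum(vapply(seq_len(m), function(i) sum((p[i, ] - q[i, ])^2), 0))
    expect_lte(dtw(p, q)$distance, diag_cost + 1e-12)
  }
})

test_that("Gaussian similarity transform behaves as exp(-lambda^2/2)", {
  s <- random_tuples(3)
  expect_equal(dtw_similarity(s, s), 1)
  # engineered lambda = sqrt(2): single-element sequences at squared distance sqrt(2)
  p <- matrix(c(2^0.25, 0, 0, 0, 0), 1)
  q <- matrix(0, 1, 5)
  expect_equal(dtw(p, q)$distance, sqrt(2), tolerance = 1e-12)
  expect_equal(dtw_similarity(p, q), exp(-1), tolerance = 1e-12)
  # monotone decreasing in lambda
  lams <- c(0.1, 0.5, 1, 2, 5)
  sims <- exp(-0.5 * lams^2)
  expect_true(all(diff(sims) < 0))
})

test_that("compiled cross matrix agrees with the R recurrence", {
  set.seed(97)
  dn1 <- dynamic_network(lapply(1:3, function(i) random_graph_edges(6, 0.4)))
  dn2 <- dynamic_network(lapply(1:4, function(i) random_graph_edges(7, 0.4)))
  f1 <- feature_sequences(dn1); f2 <- feature_sequences(dn2)
  sm <- similarity_matrix(dn1, dn2, f1, f2)
  for (u in sample(names(f1), 3)) {
    for (v in sample(names(f2), 3)) {
      res <- dtw(f1[[u]], f2[[v]])
      expect_equal(sm$distance[u, v], res$distance, tolerance = 1e-12)
      expect_equal(sm$s_t[u, v], exp(-0.5 * res$distance^2), tolerance = 1e-12)
    }
  }
})

test_that("similarity matrix covers the cross product and honors identity", {
  dn1 <- dynamic_network(list(edges_path3, edges_k3))
  dn2 <- dynamic_network(list(rbind(c("x", "y"), c("y", "z")),
                              rbind(c("x", "y"), c("y", "z"), c("x", "z"), c("z", "w"))))
  sm <- similarity_matrix(dn1, dn2)
  expect_equal(dim(sm$s_t), c(3L, 4L))
  expect_true(all(sm$s_t > 0 & sm$s_t <= 1))
  # identical copies of one network: the "diagonal" pairs are perfect matches
  sm_id <- similarity_matrix(dn1, dn1)
  expect_equal(unname(diag(sm_id$s_t)), rep(1, 3))
  expect_equal(unname(diag(sm_id$distance)), rep(0, 3))
  # permuted-isomorphic copy: s_t(v, pi(v)) = 1
  perm <- c(a = "P", b = "Q", c = "R")
  dn1p <- dynamic_network(lapply(dn1$snapshots, function(e) {
    cbind(perm[e[, 1]], perm[e[, 2]])
  }))
  smp <- similarity_matrix(dn1, dn1p)
  for (v in names(perm)) expect_equal(smp$s_t[v, perm[[v]]], 1)
})

test_that("candidate restriction masks non-candidate pairs", {
  dn1 <- dynamic_network(list(edges_path3))
  dn2 <- dynamic_network(list(rbind(c("x", "y"))))
  sm <- similarity_matrix(dn1, dn2, candidates = rbind(c("a", "x"), c("b", "y")))
  expect_equal(sum(!is.na(sm$s_t)), 2L)
  expect_equal(nrow(similarity_table(sm)), 2L)
})

test_that("path-length normalization rescales the distance before the Gaussian", {
  p <- random_tuples(5); q <- random_tuples(3)
  res <- dtw(p, q)
  expect_equal(dtw_similarity(p, q, normalize = TRUE),
               exp(-0.5 * (res$distance / nrow(res$path))^2), tolerance = 1e-12)
})
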