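# Duplication-divergence growth, confidence-ranked snapshots, and the two
# randomization (noise) schemes.

test_that("deterministic duplication-divergence limits are forced by the rules", {
  # p = 1, q = 0: duplicating either endpoint of the seed edge forms a triangle
  dn <- duplication_divergence(3, p = 1, q = 0, seed = 1)
  last <- dn$snapshots[[n_snapshots(dn)]]
  expect_equal(nrow(last), 3L)
  expect_setequal(paste(last[, 1], last[, 2]),
                  c("1 2", "1 3", "2 3"))

  # p = 0, q = 1: every duplicated link loses exactly one of its two copies,
  # so the total degree gained by the duplicate equals the degree lost by
  # the template's side: edge count is conserved at each step
  for (s in 1:5) {
    dn2 <- duplication_divergence(12, p = 0, q = 1, seed = s)
    counts <- vapply(dn2$snapshots, nrow, 0L)
    expect_true(all(counts == 1L))
  }
})

test_that("growth bookkeeping: node counts, snapshot cadence, reproducibility", {
  dn <- duplication_divergence(50, 0.3, 0.7, snapshot_every = 10, seed = 9)
  expect_equal(n_snapshots(dn), 5L)
  node_counts <- vapply(seq_len(5), function(i) length(snapshot_nodes(dn, i)), 0L)
  expect_true(all(diff(node_counts) > 0))

  # node count after s growth steps is 2 + s (isolated diverged nodes aside,
  # checked with q = 0 so nothing is ever removed)
  dn3 <- duplication_divergence(30, 0.5, 0, snapshot_every = 7, seed = 4)
  expect_equal(length(snapshot_nodes(dn3, 1)), 2L + 7L)
  expect_equal(length(snapshot_nodes(dn3, n_snapshots(dn3))), 30L)

  # bit-reproducible under a fixed seed
  a <- duplication_divergence(40, 0.7, 0.6, seed = 123)
  b <- duplication_divergence(40, 0.7, 0.6, seed = 123)
  expect_identical(a, b)
})

test_that("confidence snapshots are nested, sized by fraction, and end at the full set", {
  set.seed(8)
  pairs <- t(combn(paste0("v", 1:20), 2))
  sel <- sample(nrow(pairs), 100)
  st <- static_network(pairs[sel, ], confidence = stats::runif(100))
  dn <- confidence_snapshots(st)
  expect_equal(n_snapshots(dn), 7L)
  sizes <- vapply(dn$snapshots, nrow, 0L)
  expect_equal(sizes, c(70L, 75L, 80L, 85L, 90L, 95L, 100L))
  for (i in 1:6) {
    expect_true(all(edge_keys_for_test(dn, i) %in% edge_keys_for_test(dn, i + 1)))
  }
  expect_setequal(edge_keys_for_test(dn, 7),
                  paste(st$edges[, 1], st$edges[, 2], sep = "\r"))

  # single full-fraction snapshot reproduces the static network
  dn1 <- confidence_snapshots(st, fractions = 1.0)
  expect_equal(nrow(dn1$snapshots[[1]]), 100L)

  # equal confidences: nesting still holds via the lexicographic tie-break
  st2 <- static_network(pairs[sel, ], confidence = rep(1, 100))
  dn2 <- confidence_snapshots(st2)
  for (i in 1:6) {
    expect_true(all(edge_keys_for_test(dn2, i) %in% edge_keys_for_test(dn2, i + 1)))
  }
  expect_error(confidence_snapshots(static_network(pairs[sel, ])), "confidence")
})

test_that("transient snapshots flatten back to the source network", {
  st <- aggregate(duplication_divergence(25, 0.4, 0.5, seed = 21))
  dn <- transient_snapshots(st, n_snapshots = 6, presence = 0.4, seed = 5)
  expect_equal(n_snapshots(dn), 6L)
  expect_setequal(paste(aggregate(dn)$edges[, 1], aggregate(dn)$edges[, 2]),
                  paste(st$edges[, 1], st$edges[, 2]))
  expect_identical(dn, transient_snapshots(st, n_snapshots = 6, presence = 0.4, seed = 5))
  # snapshots genuinely differ from one another
  keys <- lapply(seq_len(6), edge_keys_for_test, dn = dn)
  expect_gt(length(unique(vapply(keys, paste, "", collapse = ";"))), 1L)
})

test_that("temporal randomization preserves counts and the aggregate exactly", {
  set.seed(61)
  for (rep in 1:6) {
    dn <- duplication_divergence(30, 0.4, 0.5, seed = 500 + rep)
    for (p in c(0, 0.3, 0.8)) {
      noisy <- randomize_temporal(dn, p, seed = rep)
      expect_equal(vapply(noisy$snapshots, nrow, 0L),
                   vapply(dn$snapshots, nrow, 0L))
      expect_setequal(paste(aggregate(noisy)$edges[, 1], aggregate(noisy)$edges[, 2]),
                      paste(aggregate(dn)$edges[, 1], aggregate(dn)$edges[, 2]))
      if (p == 0) expect_identical(noisy$snapshots, dn$snapshots)
    }
  }
})

test_that("structural randomization preserves counts and simple-graph invariants", {
  set.seed(62)
  changed_any <- FALSE
  for (rep in 1:6) {
    dn <- duplication_divergence(30, 0.4, 0.5, seed = 600 + rep)
    for (p in c(0, 0.5, 1)) {
      noisy <- randomize_structural(dn, p, seed = rep)
      expect_equal(vapply(noisy$snapshots, nrow, 0L),
                   vapply(dn$snapshots, nrow, 0L))
      for (i in seq_len(n_snapshots(noisy))) {
        e <- noisy$snapshots[[i]]
        expect_true(all(e[, 1] != e[, 2]))                   # no loops
        expect_false(anyDuplicated(edge_keys_for_test(noisy, i)) > 0)
      }
      if (p == 0) expect_identical(noisy$snapshots, dn$snapshots)
      if (p == 1 &&
          !setequal(paste(aggregate(noisy)$edges[, 1], aggregate(noisy)$edges[, 2]),
                    paste(aggregate(dn)$edges[, 1], aggregate(dn)$edges[, 2]))) {
        changed_any <- TRUE
      }
    }
  }
  # the scheme is allowed to change the flattened network, and at full
  # noise it actually does so on typical inputs
  expect_true(changed_any)
})

test_that("synthetic homology tables honor the truth mapping and the filter", {
  truth <- setNames(paste0("y", 1:15), paste0("x", 1:15))
  ht0 <- synthetic_homology(truth, n_decoys = 0, seed = 3)
  expect_setequal(paste(ht0$query, ht0$subject), paste(names(truth), truth))
  ht <- synthetic_homology(truth, n_decoys = 10, noise = 1, seed = 3)
  expect_equal(nrow(ht), 25L)
  expect_true(all(ht$evalue < 1e-7))
  # true pairs are stronger than decoys by construction
  is_true_pair <- paste(ht$query, ht$subject) %in% paste(names(truth), truth)
  expect_true(max(ht$evalue[is_true_pair]) < min(ht$evalue[!is_true_pair]) * 10)
  expect_identical(ht, synthetic_homology(truth, n_decoys = 10, noise = 1, seed = 3))
})
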