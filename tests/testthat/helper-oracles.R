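# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own dynamic-programming
# and annealing code paths.

# Minimum cumulative distance over an exhaustive enumeration of all valid
# warping paths (start (1,1), end (m,n), steps bounded by one per index).
# Sums accumulate left-to-right along each path.
brute_dtw <- function(p, q) {
  p <- rbind(p); q <- rbind(q)
  m <- nrow(p); n <- nrow(q)
  d <- function(i, j) sum((p[i, ] - q[j, ])^2)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + d(i, j)
    if (i == m && j == n) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < m && j < n) recurse(i + 1L, j + 1L, acc)
    if (i < m) recurse(i + 1L, j, acc)
    if (j < n) recurse(i, j + 1L, acc)
  }
  recurse(1L, 1L, 0)
  best
}

# All valid warping paths (as lists of index-pair matrices); used for
# structural checks at tiny sizes.
brute_dtw_paths <- function(m, n) {
  out <- list()
  recurse <- function(i, j, path) {
    path <- rbind(path, c(i, j))
    if (i == m && j == n) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    if (i < m && j < n) recurse(i + 1L, j + 1L, path)
    if (i < m) recurse(i + 1L, j, path)
    if (j < n) recurse(i, j + 1L, path)
  }
  recurse(1L, 1L, NULL)
  out
}

# Maximum total score over all one-to-one (possibly partial) matchings of
# rows to columns of a score matrix (NA = inadmissible pair).
brute_matching <- function(S) {
  n1 <- nrow(S); n2 <- ncol(S)
  recurse <- function(i, used) {
    if (i > n1) return(0)
    best <- recurse(i + 1L, used)          # leave row i unmatched
    for (j in seq_len(n2)) {
      if (!used[j] && !is.na(S[i, j])) {
        used[j] <- TRUE
        best <- max(best, S[i, j] + recurse(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  recurse(1L, rep(FALSE, n2))
}

# Number of length-2 walks between x and v that are paths (middle node
# distinct from both ends), by direct enumeration.
brute_two_step_paths <- function(edges, x, v) {
  nodes <- sort(unique(as.character(edges)))
  has_edge <- function(u, w) {
    any((edges[, 1L] == u & edges[, 2L] == w) |
          (edges[, 1L] == w & edges[, 2L] == u))
  }
  sum(vapply(setdiff(nodes, c(x, v)), function(mid) {
    has_edge(x, mid) && has_edge(mid, v)
  }, FALSE))
}

# Random simple graph on n nodes ("n1".."nn") with edge probability pe,
# guaranteed non-empty.
random_graph_edges <- function(n, pe = 0.4) {
  pairs <- t(combn(paste0("n", seq_len(n)), 2L))
  repeat {
    keep <- stats::runif(nrow(pairs)) < pe
    if (any(keep)) return(pairs[keep, , drop = FALSE])
  }
}

random_tuples <- function(m, scale = 2) {
  matrix(stats::runif(m * 5L, 0, scale), nrow = m)
}

edge_keys_for_test <- function(dn, i) {
  e <- dn$snapshots[[i]]
  paste(e[, 1], e[, 2], sep = "\r")
}

# Canonical tiny graphs.
edges_k3 <- rbind(c("a", "b"), c("a", "c"), c("b", "c"))
edges_k4 <- t(combn(c("a", "b", "c", "d"), 2L))
edges_path3 <- rbind(c("a", "b"), c("b", "c"))
edges_star5 <- cbind("hub", paste0("leaf", 1:4))
edges_c4 <- rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("a", "d"))
edges_c5 <- rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"), c("a", "e"))
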