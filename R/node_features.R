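# Per-snapshot 5-tuple topological features (gamma, sigma, tau, eta, theta)
# and per-node feature sequences across snapshots.
#
#   gamma  node reputation: entry of the L2-normalized dominant eigenvector
#          of the snapshot adjacency matrix (eigenvector centrality)
#   sigma  degree |N_v|
#   tau    sum of neighbor reputations
#   eta    number of nodes at shortest-path distance exactly 2
#   theta  1/2 * sum over two-hop nodes x of k_x * p_xv, where p_xv counts
#          the distinct length-2 paths between x and v

FEATURE_NAMES <- c("gamma", "sigma", "tau", "eta", "theta")

snapshot_adjacency <- function(edges) {
  nodes <- sort(unique(as.character(edges)))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0L) {
    ia <- match(edges[, 1L], nodes)
    ib <- match(edges[, 2L], nodes)
    A[cbind(ia, ib)] <- 1
    A[cbind(ib, ia)] <- 1
  }
  A
}

#' Node reputations: dominant eigenvector of a snapshot adjacency matrix
#'
#' Computes the L2-normalized eigenvector of the largest eigenvalue of the
#' (symmetric, non-negative) adjacency matrix of one snapshot, oriented so
#' that all entries are non-negative (the Perron-Frobenius vector). Only
#' nodes present in the snapshot (incident to an edge) receive an entry.
#'
#' For snapshots with at most 500 present nodes a full symmetric
#' eigendecomposition is used; larger snapshots use power iteration on
#' `A + I` (the shift guarantees convergence on bipartite graphs) with
#' tolerance 1e-10 and at most 10,000 iterations, started from the all-ones
#' vector.
#'
#' On disconnected snapshots the single dominant eigenvector of the whole
#' matrix is used, so nodes outside the dominant component may receive
#' reputation 0; there is deliberately one global scale per snapshot.
#'
#' @param edges Two-column character matrix of snapshot edges (or a
#'   `dynamic_network` plus snapshot position, see [feature_sequence()]).
#' @return Named numeric vector `k` over present nodes, `sum(k^2) == 1`.
#' @export
reputation_vector <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L || nrow(edges) == 0L) {
    stop("empty snapshot: reputation undefined (no adjacency spectrum)")
  }
  A <- snapshot_adjacency(canonical_edges(edges[, 1L], edges[, 2L]))
  n <- nrow(A)
  if (n <= 500L) {
    es <- eigen(A, symmetric = TRUE)
    v <- es$vectors[, 1L]
  } else {
    v <- rep(1, n)
    v <- v / sqrt(sum(v^2))
    for (it in seq_len(10000L)) {
      w <- A %*% v + v            # power step on A + I
      w <- as.numeric(w) / sqrt(sum(w^2))
      if (sqrt(sum((w - v)^2)) < 1e-10) { v <- w; break }
      v <- w
    }
  }
  if (v[which.max(abs(v))] < 0) v <- -v
  v[v < 0 & v > -1e-12] <- 0      # clamp numerical noise on the zero entries
  names(v) <- rownames(A)
  v
}

#' Nodes exactly two steps away from a node in a snapshot
#'
#' Returns the set of nodes at shortest-path distance exactly 2 from `v`:
#' neighbors of neighbors that are neither `v` itself nor directly connected
#' to `v`.
#'
#' @param edges Two-column edge matrix of the snapshot.
#' @param v Node id; must be present in the snapshot.
#' @return Sorted character vector (possibly empty).
#' @export
two_hop_set <- function(edges, v) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  nb <- neighbors_of(edges, v)
  if (length(nb) == 0L) stop("node '", v, "' is not present in the snapshot")
  second <- unique(unlist(lapply(nb, neighbors_of, edges = edges), use.names = FALSE))
  sort(setdiff(second, c(v, nb)))
}

neighbors_of <- function(edges, v) {
  sel1 <- edges[, 1L] == v
  sel2 <- edges[, 2L] == v
  unique(c(edges[sel2, 1L], edges[sel1, 2L]))
}

#' Number of shortest paths between a node and a two-hop neighbor
#'
#' For `x` at shortest-path distance exactly 2 from `v`, the shortest paths
#' are precisely the length-2 paths, so the count is the number of common
#' neighbors of `x` and `v`.
#'
#' @param edges Two-column edge matrix of the snapshot.
#' @param x,v Node ids with `x` at distance exactly 2 from `v`.
#' @return Integer count (>= 1).
#' @export
shortest_path_count <- function(edges, x, v) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (!(x %in% two_hop_set(edges, v))) {
    stop("node '", x, "' is not at distance 2 from '", v, "'")
  }
  length(intersect(neighbors_of(edges, x), neighbors_of(edges, v)))
}

# All 5-tuples of one snapshot at once, as an n x 5 matrix over present
# nodes.  Matrix form: with A the adjacency, A2 = A %*% A counts length-2
# walks, the two-hop indicator is (A2 > 0) & (A == 0) off-diagonal, and
#   tau = A k,   eta = rowSums(M2),   theta = 0.5 * (M2 * A2) %*% k.
snapshot_feature_matrix <- function(edges) {
  A <- snapshot_adjacency(edges)
  k <- reputation_vector(edges)
  k <- k[rownames(A)]
  A2 <- A %*% A
  M2 <- (A2 > 0) & (A == 0)
  diag(M2) <- FALSE
  feats <- cbind(
    gamma = as.numeric(k),
    sigma = rowSums(A),
    tau   = as.numeric(A %*% k),
    eta   = rowSums(M2),
    theta = 0.5 * as.numeric((M2 * A2) %*% k)
  )
  rownames(feats) <- rownames(A)
  feats
}

#' Compute the 5-tuple feature vector of one node in one snapshot
#'
#' @param edges Two-column edge matrix of the snapshot.
#' @param v Node id, present in the snapshot.
#' @param reputation Optional precomputed [reputation_vector()] for this
#'   snapshot; computed on the fly if missing.
#' @return Named numeric vector `(gamma, sigma, tau, eta, theta)`.
#' @export
feature_tuple <- function(edges, v, reputation = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  edges <- canonical_edges(edges[, 1L], edges[, 2L])
  if (is.null(reputation)) reputation <- reputation_vector(edges)
  nb <- neighbors_of(edges, v)
  if (length(nb) == 0L) stop("node '", v, "' is not present in the snapshot")
  n2 <- two_hop_set(edges, v)
  theta <- if (length(n2) == 0L) 0 else {
    0.5 * sum(vapply(n2, function(x) {
      reputation[[x]] * shortest_path_count(edges, x, v)
    }, 0))
  }
  c(gamma = unname(reputation[[v]]),
    sigma = length(nb),
    tau   = sum(reputation[nb]),
    eta   = length(n2),
    theta = theta)
}

#' Feature sequence of one node across the snapshots of a dynamic network
#'
#' The node's time sequence: one 5-tuple per snapshot in which the node is
#' present (has at least one incident edge), in ascending snapshot order.
#' Nodes of a dynamic network appear in at least one snapshot, so every
#' sequence has length >= 1.
#'
#' @param dn A `dynamic_network`.
#' @param v Node id in the node universe of `dn`.
#' @return A numeric matrix with columns `(gamma, sigma, tau, eta, theta)`,
#'   one row per presence, with attribute `snapshots` giving the 0-based
#'   snapshot indices.
#' @export
feature_sequence <- function(dn, v) {
  if (!(v %in% dn$nodes)) stop("unknown node '", v, "'")
  feature_sequences(dn)[[v]]
}

#' Feature sequences for every node of a dynamic network
#'
#' @param dn A `dynamic_network`.
#' @return Named list over `dn$nodes`; each element as in
#'   [feature_sequence()].
#' @export
feature_sequences <- function(dn) {
  per_snap <- lapply(dn$snapshots, function(e) {
    if (nrow(e) == 0L) NULL else snapshot_feature_matrix(e)
  })
  out <- vector("list", length(dn$nodes))
  names(out) <- dn$nodes
  for (v in dn$nodes) {
    rows <- list()
    snaps <- integer(0)
    for (i in seq_along(per_snap)) {
      fm <- per_snap[[i]]
      if (!is.null(fm) && v %in% rownames(fm)) {
        rows[[length(rows) + 1L]] <- fm[v, ]
        snaps <- c(snaps, i - 1L)
      }
    }
    m <- do.call(rbind, rows)
    colnames(m) <- FEATURE_NAMES
    rownames(m) <- NULL
    attr(m, "snapshots") <- snaps
    out[[v]] <- m
  }
  out
}

#' Dump feature sequences as a long-format data.frame
#'
#' Inspection/debugging helper: one row per (node, snapshot) presence with
#' the five feature values.
#'
#' @param dn A `dynamic_network`.
#' @return data.frame with columns `node`, `snapshot`, `gamma`, `sigma`,
#'   `tau`, `eta`, `theta`.
#' @export
feature_table <- function(dn) {
  fs <- feature_sequences(dn)
  do.call(rbind, lapply(names(fs), function(v) {
    m <- fs[[v]]
    data.frame(node = v, snapshot = attr(m, "snapshots"),
               as.data.frame(m), stringsAsFactors = FALSE)
  }))
}
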