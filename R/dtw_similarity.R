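# Dynamic time warping between per-node feature sequences, the Gaussian
# similarity transform s_t = exp(-lambda^2 / 2), and the full cross-network
# similarity matrix.

#' Squared-Euclidean distance between two 5-tuple feature vectors
#'
#' The local cost of the warping grid: the sum of squared element-wise
#' differences over the five components (no square root).
#'
#' @param p,q Numeric vectors of length 5.
#' @return Non-negative real.
#' @export
tuple_distance <- function(p, q) sum((p - q)^2)

#' Dynamic time warping distance and path between two feature sequences
#'
#' Computes the cumulative-distance recurrence
#' `lambda(i,j) = d(p_i, q_j) + min(lambda(i-1,j-1), lambda(i-1,j), lambda(i,j-1))`
#' with local cost [tuple_distance()], and recovers one optimal warping path
#' by backtracking. The path starts at (1,1), ends at (m,n), moves by steps
#' of at most one in each index, and has length between `max(m,n)` and
#' `m + n - 1`. Backtracking ties are broken deterministically: diagonal
#' first, then the step decreasing the row index, then the column step.
#'
#' @param p,q Numeric matrices (rows = time points, columns = features),
#'   e.g. from [feature_sequence()]; both must have at least one row and the
#'   same number of columns.
#' @return List with `distance` (the cumulative DTW distance `lambda(m,n)`)
#'   and `path` (a k x 2 integer matrix of 1-based index pairs).
#' @export
dtw <- function(p, q) {
  p <- rbind(p); q <- rbind(q)
  m <- nrow(p); n <- nrow(q)
  if (m == 0L || n == 0L) stop("dtw requires non-empty sequences")
  if (ncol(p) != ncol(q)) stop("feature dimensions differ")
  d <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) d[i, j] <- sum((p[i, ] - q[j, ])^2)
  lam <- matrix(Inf, m + 1L, n + 1L)
  lam[1L, 1L] <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      lam[i + 1L, j + 1L] <- d[i, j] + min(lam[i, j], lam[i, j + 1L], lam[i + 1L, j])
    }
  }
  # backtrack from (m, n); tie-break: diagonal, then up (i-1), then left (j-1)
  path <- matrix(0L, m + n - 1L, 2L)
  i <- m; j <- n; k <- 0L
  repeat {
    k <- k + 1L
    path[k, ] <- c(i, j)
    if (i == 1L && j == 1L) break
    preds <- c(lam[i, j], lam[i, j + 1L], lam[i + 1L, j])   # diag, up, left
    sel <- which.min(preds)      # first minimum = the tie-break order
    if (sel == 1L) { i <- i - 1L; j <- j - 1L }
    else if (sel == 2L) { i <- i - 1L }
    else { j <- j - 1L }
  }
  list(distance = lam[m + 1L, n + 1L],
       path = path[k:1L, , drop = FALSE])
}

#' Gaussian time-warp similarity of two feature sequences
#'
#' Transforms the DTW distance lambda into a similarity
#' `s_t = exp(-lambda^2 / 2)`, which lies in (0, 1] and equals 1 exactly
#' when the sequences are identical.
#'
#' With `normalize = TRUE`, lambda is first divided by the warping-path
#' length; this is off by default (the plain distance is used as printed in
#' the method), but is useful because the unnormalized lambda drives `s_t`
#' numerically to 0 for long, far-apart sequences.
#'
#' @param p,q Feature-sequence matrices, as for [dtw()].
#' @param normalize Divide the DTW distance by the warping-path length
#'   before the Gaussian transform (default `FALSE`).
#' @return Similarity in (0, 1].
#' @export
dtw_similarity <- function(p, q, normalize = FALSE) {
  res <- dtw(p, q)
  lambda <- res$distance
  if (normalize) lambda <- lambda / nrow(res$path)
  exp(-0.5 * lambda^2)
}

#' Cross-network time-warp similarity matrix
#'
#' For every pair (u in network 1, v in network 2) — or only the pairs in
#' `candidates` when given — computes the DTW distance between the nodes'
#' feature sequences and its Gaussian similarity.
#'
#' @param dn1,dn2 `dynamic_network` objects.
#' @param features1,features2 Optional precomputed [feature_sequences()]
#'   lists (computed on the fly if missing).
#' @param candidates Optional two-column matrix/data.frame of (node1, node2)
#'   pairs restricting the computation; entries outside it are `NA`.
#' @param normalize Passed to the Gaussian transform, see
#'   [dtw_similarity()].
#' @return List of class `similarity_matrix` with numeric matrices
#'   `distance` and `s_t` (rows = nodes of `dn1`, columns = nodes of `dn2`).
#' @export
similarity_matrix <- function(dn1, dn2, features1 = NULL, features2 = NULL,
                              candidates = NULL, normalize = FALSE) {
  if (is.null(features1)) features1 <- feature_sequences(dn1)
  if (is.null(features2)) features2 <- feature_sequences(dn2)
  n1 <- names(features1); n2 <- names(features2)
  res <- dtw_cross_cpp(unname(features1), unname(features2))
  D <- res$distance
  K <- res$path_len
  dimnames(D) <- dimnames(K) <- list(n1, n2)
  if (!is.null(candidates)) {
    candidates <- as.matrix(candidates)
    keep <- matrix(FALSE, length(n1), length(n2), dimnames = list(n1, n2))
    keep[cbind(match(candidates[, 1L], n1), match(candidates[, 2L], n2))] <- TRUE
    D[!keep] <- NA_real_
  }
  lambda <- if (normalize) D / K else D
  st <- exp(-0.5 * lambda^2)
  structure(list(distance = D, s_t = st, normalize = normalize),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d node pairs%s\n",
              nrow(x$s_t), ncol(x$s_t),
              if (x$normalize) " (path-length-normalized DTW)" else ""))
  invisible(x)
}

#' Dump a similarity matrix as a long-format data.frame
#'
#' @param sm A `similarity_matrix`.
#' @return data.frame with columns `node1`, `node2`, `dtw_distance`, `s_t`
#'   (candidate pairs only, if the matrix was restricted).
#' @export
similarity_table <- function(sm) {
  idx <- which(!is.na(sm$distance), arr.ind = TRUE)
  data.frame(node1 = rownames(sm$distance)[idx[, 1L]],
             node2 = colnames(sm$distance)[idx[, 2L]],
             dtw_distance = sm$distance[idx],
             s_t = sm$s_t[idx],
             stringsAsFactors = FALSE)
}
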