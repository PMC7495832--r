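# Synthetic benchmark machinery: duplication-divergence growth of dynamic
# PPI-like networks, confidence-ranked snapshot sequences from a weighted
# static network, the two edge-swap randomization (noise) schemes, and a
# synthetic homology-table generator with known ground-truth orthologs.

key_to_edges <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(character(0), ncol = 2L))
  }
  do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
}

#' Grow a dynamic network by gene duplication and divergence
#'
#' Starts from a seed of two connected nodes and adds one node per growth
#' step. Each step: a template node `i` is picked uniformly at random; a
#' duplicate `i'` is created with links to all neighbors of `i`; with
#' probability `p` the link (i, i') is added; then, for each node `j` linked
#' to both `i` and `i'` (the duplicated links), one of (i, j) / (i', j) is
#' chosen uniformly and removed with probability `q`. A snapshot (copy of
#' the current edge set) is recorded every `snapshot_every` steps and at the
#' final step, so the snapshots form a growing sequence. A duplicate that
#' loses all its links is kept in the growth trace but, being isolated, does
#' not appear in the resulting network's node universe.
#'
#' @param n_final Target node count of the grown network (>= 2).
#' @param p Probability of the duplicate-template link, in [0, 1].
#' @param q Divergence (duplicated-link removal) probability, in [0, 1].
#' @param snapshot_every Growth steps between recorded snapshots; default
#'   `ceiling((n_final - 2) / 5)`, i.e. 5 evenly spaced snapshots.
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @return A `dynamic_network` whose snapshots are nested growth stages;
#'   node ids are `"1" ... "n_final"` in creation order.
#' @export
duplication_divergence <- function(n_final, p, q, snapshot_every = NULL,
                                   seed = NULL) {
  stopifnot(n_final >= 2, p >= 0, p <= 1, q >= 0, q <= 1)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  steps <- n_final - 2L
  if (is.null(snapshot_every)) snapshot_every <- max(1L, ceiling(steps / 5))
  stopifnot(snapshot_every >= 1L)
  adj <- vector("list", n_final)
  adj[[1L]] <- 2L
  adj[[2L]] <- 1L
  n_cur <- 2L
  record <- function() {
    rows <- lapply(seq_len(n_cur), function(i) {
      nb <- adj[[i]]
      nb <- nb[nb > i]
      if (length(nb) == 0L) NULL else cbind(as.character(i), as.character(nb))
    })
    do.call(rbind, rows)
  }
  snaps <- list()
  for (s in seq_len(steps)) {
    i <- sample.int(n_cur, 1L)
    i2 <- n_cur + 1L
    nb <- adj[[i]]
    adj[[i2]] <- nb
    for (j in nb) adj[[j]] <- c(adj[[j]], i2)
    if (stats::runif(1) < p) {
      adj[[i]] <- c(adj[[i]], i2)
      adj[[i2]] <- c(adj[[i2]], i)
    }
    for (j in nb) {                    # divergence over the duplicated links
      drop_from <- if (stats::runif(1) < 0.5) i else i2
      if (stats::runif(1) < q) {
        adj[[drop_from]] <- setdiff(adj[[drop_from]], j)
        adj[[j]] <- setdiff(adj[[j]], drop_from)
      }
    }
    n_cur <- i2
    if (s %% snapshot_every == 0L || s == steps) {
      snaps[[length(snaps) + 1L]] <- record()
    }
  }
  if (steps == 0L) snaps <- list(record())
  dynamic_network(snaps)
}

#' Build a dynamic network of confidence-ranked nested snapshots
#'
#' Emulates the construction of an artificial temporal sequence from a
#' confidence-weighted static PPI network: snapshot k contains the top
#' `ceiling(fraction_k * |E|)` edges ranked by descending confidence (ties
#' broken by lexicographic edge order), so the snapshots are nested and the
#' last one equals the full network when the final fraction is 1.
#'
#' @param static A `static_network` with confidence weights.
#' @param fractions Ascending fractions in (0, 1]; the default
#'   `seq(0.70, 1.00, by = 0.05)` yields seven snapshots from 70% to 100%
#'   of the interactions.
#' @return A `dynamic_network` with `length(fractions)` snapshots.
#' @export
confidence_snapshots <- function(static, fractions = seq(0.70, 1.00, by = 0.05)) {
  if (is.null(static$confidence)) {
    stop("static network has no confidence weights")
  }
  stopifnot(length(fractions) >= 1L, all(fractions > 0), all(fractions <= 1),
            !is.unsorted(fractions, strictly = TRUE))
  e <- static$edges
  ord <- order(-static$confidence, e[, 1L], e[, 2L])
  n_edges <- nrow(e)
  snaps <- lapply(fractions, function(f) {
    e[ord[seq_len(ceiling(f * n_edges))], , drop = FALSE]
  })
  dynamic_network(snaps)
}

#' Build a dynamic network of transient interactions from a static network
#'
#' Emulates transient interactions: each edge of the static network is
#' present in each of `n_snapshots` snapshots independently with
#' probability `presence`, and every edge is forced into at least one
#' (uniformly chosen) snapshot, so the aggregated (flattened) version of
#' the result is exactly the input network. Unlike the nested
#' confidence-ranked construction of [confidence_snapshots()], the
#' resulting snapshots genuinely differ from each other, which makes the
#' sequence a meaningful substrate for the temporal randomization scheme
#' (on a strictly nested sequence every count-preserving edge swap would
#' create a duplicate in its destination snapshot, so
#' [randomize_temporal()] degenerates to the identity there).
#'
#' @param static A `static_network`.
#' @param n_snapshots Number of snapshots (>= 2).
#' @param presence Per-snapshot presence probability of each edge.
#' @param seed Optional integer seed.
#' @return A `dynamic_network` with `n_snapshots` snapshots.
#' @export
transient_snapshots <- function(static, n_snapshots = 7L, presence = 0.5,
                                seed = NULL) {
  stopifnot(n_snapshots >= 2L, presence > 0, presence <= 1)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n_e <- nrow(static$edges)
  pres <- matrix(stats::runif(n_e * n_snapshots) < presence, n_e, n_snapshots)
  none <- which(rowSums(pres) == 0L)
  if (length(none) > 0L) {
    pres[cbind(none, sample.int(n_snapshots, length(none), replace = TRUE))] <- TRUE
  }
  dynamic_network(lapply(seq_len(n_snapshots), function(k) {
    static$edges[pres[, k], , drop = FALSE]
  }))
}

pick_other_snapshot <- function(n, i) {
  j <- sample.int(n - 1L, 1L)
  if (j >= i) j + 1L else j
}

#' Randomize only the temporal aspect of a dynamic network
#'
#' For each edge `e_ab` of each snapshot `g_i`, with probability `p` a
#' uniformly random edge `e_cd` of a uniformly random other snapshot `g_j`
#' is selected and the two interactions swap snapshots: `e_ab` moves to
#' `g_j` and `e_cd` to `g_i`. A swap that would duplicate an edge already
#' present in its destination snapshot is resampled (up to `max_retries`
#' times, then skipped). Per-snapshot edge counts are preserved, and the
#' aggregated (flattened) static network is exactly that of the input —
#' only the timing information is scrambled.
#'
#' @param dn A `dynamic_network` with >= 2 snapshots.
#' @param p Noise level in [0, 1].
#' @param seed Optional integer seed.
#' @param max_retries Resampling bound per edge (default 100).
#' @return A `dynamic_network`.
#' @export
randomize_temporal <- function(dn, p, seed = NULL, max_retries = 100L) {
  stopifnot(p >= 0, p <= 1, n_snapshots(dn) >= 2L)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  snaps <- lapply(dn$snapshots, edge_keys)
  n_snap <- length(snaps)
  for (i in seq_len(n_snap)) {
    for (e in snaps[[i]]) {            # frozen at visit time
      if (!(e %in% snaps[[i]])) next   # already swapped away
      if (stats::runif(1) >= p) next
      for (r in seq_len(max_retries)) {
        j <- pick_other_snapshot(n_snap, i)
        if (length(snaps[[j]]) == 0L) next
        f <- snaps[[j]][sample.int(length(snaps[[j]]), 1L)]
        if (f %in% snaps[[i]] || e %in% snaps[[j]]) next
        snaps[[i]] <- c(setdiff(snaps[[i]], e), f)
        snaps[[j]] <- c(setdiff(snaps[[j]], f), e)
        break
      }
    }
  }
  dynamic_network(lapply(snaps, key_to_edges))
}

#' Randomize both the temporal and the structural aspect
#'
#' For each edge `e_ab` of snapshot `g_i`, with probability `p` a random
#' edge `e_cd` of a random other snapshot `g_j` is selected; if the rewired
#' edges a-d and b-c are loop-free and not already present in their
#' destination snapshots, `e_ab` and `e_cd` are removed and a-d is added to
#' `g_i`, b-c to `g_j`. Invalid proposals (loop or duplicate) are undone and
#' resampled, up to `max_retries` times, then the edge is skipped.
#' Per-snapshot edge counts are preserved, but the aggregated static network
#' generally changes.
#'
#' @inheritParams randomize_temporal
#' @return A `dynamic_network`.
#' @export
randomize_structural <- function(dn, p, seed = NULL, max_retries = 100L) {
  stopifnot(p >= 0, p <= 1, n_snapshots(dn) >= 2L)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  snaps <- lapply(dn$snapshots, edge_keys)
  n_snap <- length(snaps)
  for (i in seq_len(n_snap)) {
    for (e in snaps[[i]]) {
      if (!(e %in% snaps[[i]])) next
      if (stats::runif(1) >= p) next
      ab <- strsplit(e, "\r", fixed = TRUE)[[1L]]
      for (r in seq_len(max_retries)) {
        j <- pick_other_snapshot(n_snap, i)
        if (length(snaps[[j]]) == 0L) next
        f <- snaps[[j]][sample.int(length(snaps[[j]]), 1L)]
        if (f == e) next
        cd <- strsplit(f, "\r", fixed = TRUE)[[1L]]
        if (stats::runif(1) < 0.5) cd <- rev(cd)
        a <- ab[1L]; b <- ab[2L]; c_ <- cd[1L]; d <- cd[2L]
        if (a == d || b == c_) next                      # loop
        new_i <- edge_keys(canonical_edges(a, d))
        new_j <- edge_keys(canonical_edges(b, c_))
        if (new_i %in% setdiff(snaps[[i]], e)) next      # multiple link
        if (new_j %in% setdiff(snaps[[j]], f)) next
        snaps[[i]] <- c(setdiff(snaps[[i]], e), new_i)
        snaps[[j]] <- c(setdiff(snaps[[j]], f), new_j)
        break
      }
    }
  }
  dynamic_network(lapply(snaps, key_to_edges))
}

#' Generate a synthetic homology table with known ground truth
#'
#' Fixture generator: emits BLAST-like candidate pairs for a known
#' one-to-one ortholog mapping so that node-correctness experiments need no
#' sequences. True pairs get e-values log-uniform in `[1e-60, 1e-20]` (plus
#' optional log10-scale jitter), decoy pairs log-uniform in `[1e-12, 1e-8]`;
#' every emitted e-value is below the conventional 1e-7 candidate filter.
#' Bit-scores are generated as an increasing function of the e-value
#' exponent.
#'
#' @param truth Named character vector (`names` = network-1 nodes, values =
#'   their true network-2 partners) or a two-column matrix.
#' @param n_decoys Number of random non-true cross pairs to add.
#' @param noise Standard deviation of Gaussian jitter on the true pairs'
#'   log10 e-values (clamped below the filter threshold).
#' @param seed Optional integer seed.
#' @return A `homology_table`.
#' @export
synthetic_homology <- function(truth, n_decoys = 0L, noise = 0, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (is.matrix(truth)) truth <- stats::setNames(truth[, 2L], truth[, 1L])
  u <- names(truth); v <- unname(truth)
  if (anyDuplicated(u) || anyDuplicated(v)) stop("truth mapping must be one-to-one")
  log_ev <- stats::runif(length(u), -60, -20)
  if (noise > 0) log_ev <- pmin(log_ev + stats::rnorm(length(u), 0, noise), -7.5)
  q <- u; s <- v
  if (n_decoys > 0L) {
    true_key <- paste(u, v, sep = "\r")
    dq <- character(0); ds <- character(0)
    guard <- 0L
    while (length(dq) < n_decoys && guard < 50L * n_decoys + 100L) {
      guard <- guard + 1L
      cand_q <- u[sample.int(length(u), 1L)]
      cand_s <- v[sample.int(length(v), 1L)]
      k <- paste(cand_q, cand_s, sep = "\r")
      if (k %in% true_key || k %in% paste(dq, ds, sep = "\r")) next
      dq <- c(dq, cand_q); ds <- c(ds, cand_s)
    }
    log_ev <- c(log_ev, stats::runif(length(dq), -12, -8))
    q <- c(q, dq); s <- c(s, ds)
  }
  evalue <- 10^log_ev
  bitscore <- round(30 - 2 * log_ev + stats::runif(length(log_ev), 0, 5), 1)
  homology_table(q, s, evalue, bitscore)
}
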