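# End-to-end benchmark orchestration: the synthetic network-pair
# classification experiment and the noise (randomization) experiment.

#' Derive independent child seeds from a master seed
#'
#' Deterministic fan-out: seeds the R RNG with the master seed and draws
#' `n` integers uniformly below 2^31 - 1. Each child seed can then seed an
#' independent, individually reproducible sub-run.
#'
#' @param master Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
child_seeds <- function(master, n) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(master)
  sample.int(2147483646L, n)
}

#' Synthetic network-pair classification benchmark
#'
#' Generates `n_per_model` dynamic networks from each of two
#' duplication-divergence parameter sets, aligns every unordered pair of
#' generated networks, scores each network pair by the alignment objective
#' normalized by the number of matched pairs, labels within-model pairs as
#' the positive ("similar") class, and evaluates the induced classifier by
#' AUPR, F-scores and AUROC. The default parameter sets are
#' (p = 0.3, q = 0.7) and (p = 0.7, q = 0.6); with the default
#' `n_per_model = 10` the run performs `choose(20, 2) = 190` alignments.
#'
#' @param model_a,model_b Lists with elements `p` and `q`: the two
#'   duplication-divergence parameter sets.
#' @param n_per_model Networks generated per parameter set (>= 2).
#' @param n_final Nodes per generated network.
#' @param snapshot_every Growth steps between snapshots (default: 5 evenly
#'   spaced snapshots; see [duplication_divergence()]).
#' @param alpha Weight on the sequence component (no homology is used here,
#'   so `alpha` only rescales scores and does not change the ranking).
#' @param params An [sa_params()] schedule template; each alignment runs
#'   with its own child seed derived from `seed`.
#' @param dtw_normalize Passed to [similarity_matrix()].
#' @param seed Master seed; fans out to per-network and per-alignment child
#'   seeds via [child_seeds()].
#' @return List of class `benchmark_report`: `pairs` (one row per aligned
#'   network pair with objective, matched-pair count, normalized score and
#'   label), `metrics` (`aupr`, `f_cross`, `f_max`, `auroc`, `prevalence`),
#'   `pr` and `roc` curves, and the configuration.
#' @export
run_benchmark <- function(model_a = list(p = 0.3, q = 0.7),
                          model_b = list(p = 0.7, q = 0.6),
                          n_per_model = 10L, n_final = 100L,
                          snapshot_every = NULL, alpha = 0.5,
                          params = sa_params(), dtw_normalize = FALSE,
                          seed = 1L) {
  stopifnot(n_per_model >= 2L)
  n_nets <- 2L * n_per_model
  n_pairs <- choose(n_nets, 2L)
  seeds <- child_seeds(seed, n_nets + n_pairs)
  net_seeds <- seeds[seq_len(n_nets)]
  aln_seeds <- seeds[n_nets + seq_len(n_pairs)]
  model_of <- rep(c("A", "B"), each = n_per_model)
  nets <- vector("list", n_nets)
  for (i in seq_len(n_nets)) {
    mp <- if (model_of[i] == "A") model_a else model_b
    nets[[i]] <- duplication_divergence(n_final, mp$p, mp$q,
                                        snapshot_every = snapshot_every,
                                        seed = net_seeds[i])
  }
  feats <- lapply(nets, feature_sequences)
  rows <- vector("list", n_pairs)
  k <- 0L
  for (i in seq_len(n_nets - 1L)) {
    for (j in seq.int(i + 1L, n_nets)) {
      k <- k + 1L
      sm <- similarity_matrix(nets[[i]], nets[[j]],
                              features1 = feats[[i]], features2 = feats[[j]],
                              normalize = dtw_normalize)
      cs <- candidate_set(sm, alpha = alpha, policy = "all")
      p_sa <- params
      p_sa$seed <- aln_seeds[k]
      aln <- anneal(cs, p_sa)
      obj <- alignment_objective(aln)
      rows[[k]] <- data.frame(
        net1 = i, net2 = j, model1 = model_of[i], model2 = model_of[j],
        label = model_of[i] == model_of[j],
        objective = obj, n_matched = nrow(aln),
        score = if (nrow(aln) == 0L) 0 else obj / nrow(aln),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  pr <- pr_curve(pairs$score, pairs$label)
  fx <- f_cross_and_max(pr)
  roc <- roc_curve(pairs$score, pairs$label)
  structure(list(
    pairs = pairs,
    metrics = list(aupr = aupr(pr), f_cross = fx$f_cross, f_max = fx$f_max,
                   auroc = auroc(pairs$score, pairs$label),
                   prevalence = mean(pairs$label)),
    pr = pr, roc = roc,
    config = list(model_a = model_a, model_b = model_b,
                  n_per_model = n_per_model, n_final = n_final,
                  alpha = alpha, seed = seed)
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0(
    "<benchmark_report> %d network pairs (prevalence %.3f)\n",
    "  AUPR    %.3f\n  F_cross %.3f\n  F_max   %.3f\n  AUROC   %.3f\n"),
    nrow(x$pairs), m$prevalence, m$aupr, m$f_cross, m$f_max, m$auroc))
  invisible(x)
}

#' Noise-robustness experiment on one dynamic network
#'
#' For each noise level, produces a randomized copy of `base_dn` (temporal
#' or temporal+structural scheme), aligns the noisy copy against the
#' original (the identity mapping is the ground truth, since node ids are
#' preserved), and reports the normalized alignment score and node
#' correctness. For contrast, the aggregated (flattened) static versions
#' are aligned as well — as single-snapshot dynamic networks — with one
#' shared annealing seed across levels, so that under temporal-only noise
#' (which leaves the aggregate unchanged) the static score is exactly
#' constant.
#'
#' @param base_dn A `dynamic_network` with >= 2 snapshots.
#' @param mode `"temporal"` or `"structural"` randomization.
#' @param p_levels Numeric vector of noise levels in [0, 1].
#' @param alpha,params,dtw_normalize As in [run_benchmark()].
#' @param seed Master seed (fans out per level).
#' @param include_static Also align the aggregated static versions.
#' @return List of class `noise_report` with `results` (one row per level
#'   and method: `noise_p`, `method`, `objective`, `n_matched`, `score`,
#'   `node_correctness`) and the configuration.
#' @export
run_noise_experiment <- function(base_dn, mode = c("temporal", "structural"),
                                 p_levels = seq(0.1, 0.9, by = 0.2),
                                 alpha = 0.5, params = sa_params(),
                                 dtw_normalize = FALSE, seed = 1L,
                                 include_static = TRUE) {
  mode <- match.arg(mode)
  n_lev <- length(p_levels)
  seeds <- child_seeds(seed, 2L * n_lev + 1L)
  noise_seeds <- seeds[seq_len(n_lev)]
  aln_seeds <- seeds[n_lev + seq_len(n_lev)]
  static_seed <- seeds[2L * n_lev + 1L]
  truth <- stats::setNames(base_dn$nodes, base_dn$nodes)
  feats_orig <- feature_sequences(base_dn)
  base_static <- aggregate(base_dn)
  base_static_dn <- dynamic_network(list(base_static$edges))
  feats_static_orig <- feature_sequences(base_static_dn)
  randomizer <- if (mode == "temporal") randomize_temporal else randomize_structural
  rows <- list()
  for (li in seq_len(n_lev)) {
    p <- p_levels[li]
    noisy <- randomizer(base_dn, p, seed = noise_seeds[li])
    sm <- similarity_matrix(noisy, base_dn, features2 = feats_orig,
                            normalize = dtw_normalize)
    cs <- candidate_set(sm, alpha = alpha, policy = "all")
    p_sa <- params; p_sa$seed <- aln_seeds[li]
    aln <- anneal(cs, p_sa)
    obj <- alignment_objective(aln)
    rows[[length(rows) + 1L]] <- data.frame(
      noise_p = p, method = "dynamic", objective = obj,
      n_matched = nrow(aln),
      score = if (nrow(aln) == 0L) 0 else obj / nrow(aln),
      node_correctness = node_correctness(aln, truth),
      stringsAsFactors = FALSE)
    if (include_static) {
      noisy_static <- dynamic_network(list(aggregate(noisy)$edges))
      sm_s <- similarity_matrix(noisy_static, base_static_dn,
                                features2 = feats_static_orig,
                                normalize = dtw_normalize)
      cs_s <- candidate_set(sm_s, alpha = alpha, policy = "all")
      p_sa_s <- params; p_sa_s$seed <- static_seed
      aln_s <- anneal(cs_s, p_sa_s)
      obj_s <- alignment_objective(aln_s)
      rows[[length(rows) + 1L]] <- data.frame(
        noise_p = p, method = "static", objective = obj_s,
        n_matched = nrow(aln_s),
        score = if (nrow(aln_s) == 0L) 0 else obj_s / nrow(aln_s),
        node_correctness = node_correctness(aln_s, truth),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(results = do.call(rbind, rows),
                 config = list(mode = mode, p_levels = p_levels,
                               alpha = alpha, seed = seed)),
            class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("<noise_report> mode=%s, %d level(s)\n",
              x$config$mode, length(x$config$p_levels)))
  print(x$results, row.names = FALSE)
  invisible(x)
}
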