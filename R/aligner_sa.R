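# One-to-one global alignment of two networks: candidate pair scoring
# (alpha * s_h + (1 - alpha) * s_t), a greedy seed, and simulated annealing
# over the match set. The objective f(A) is the sum of pair scores over the
# matched pairs.

#' Combined score of one candidate node pair
#'
#' `alpha * s_h + (1 - alpha) * s_t`: a convex blend of sequence-based and
#' time-warp similarity. Pairs admitted without homology evidence have
#' `s_h = 0`.
#'
#' @param s_h,s_t Numeric (vectors): similarity components in [0, 1].
#' @param alpha Weight in [0, 1] on the sequence component.
#' @return Numeric pair score(s).
#' @export
pair_score <- function(s_h, s_t, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  alpha * s_h + (1 - alpha) * s_t
}

#' Construct a candidate set of admissible alignment pairs
#'
#' Assembles the admissible cross-network node pairs with their per-pair
#' score components. With `policy = "homologs"` only pairs of the (filtered)
#' homology candidate set are admissible; with `"all"` the full cross
#' product of the similarity matrix is used, with `s_h = 0` where no
#' homology evidence exists.
#'
#' @param sm A [similarity_matrix()] (possibly already restricted).
#' @param homology Optional output of [normalize_scores()] (columns `query`,
#'   `subject`, `s_h`).
#' @param alpha Weight on the sequence component.
#' @param policy `"all"` or `"homologs"`.
#' @return Object of class `candidate_set`: data.frame with columns `node1`,
#'   `node2`, `s_h`, `s_t`, `score`, plus attributes `nodes1`, `nodes2`,
#'   `alpha`.
#' @export
candidate_set <- function(sm, homology = NULL, alpha = 0.5,
                          policy = c("all", "homologs")) {
  policy <- match.arg(policy)
  st_tab <- similarity_table(sm)
  sh <- stats::setNames(numeric(nrow(st_tab)), NULL)
  key <- paste(st_tab$node1, st_tab$node2, sep = "\r")
  if (!is.null(homology)) {
    hkey <- paste(homology$query, homology$subject, sep = "\r")
    hit <- match(key, hkey)
    sh[!is.na(hit)] <- homology$s_h[hit[!is.na(hit)]]
  }
  keep <- rep(TRUE, nrow(st_tab))
  if (policy == "homologs") {
    if (is.null(homology)) stop("policy 'homologs' requires a homology table")
    keep <- key %in% paste(homology$query, homology$subject, sep = "\r")
  }
  candidate_pairs(st_tab$node1[keep], st_tab$node2[keep],
                  s_h = sh[keep], s_t = st_tab$s_t[keep], alpha = alpha,
                  nodes1 = rownames(sm$s_t), nodes2 = colnames(sm$s_t))
}

#' Construct a candidate set directly from pair scores
#'
#' Low-level constructor, useful for benchmarks on synthetic score tables.
#'
#' @param node1,node2 Character vectors of admissible pairs (parallel).
#' @param s_h,s_t Numeric similarity components per pair.
#' @param alpha Weight on the sequence component.
#' @param nodes1,nodes2 Optional full node sets of the two networks
#'   (defaults to the nodes occurring in the pairs).
#' @return A `candidate_set`.
#' @export
candidate_pairs <- function(node1, node2, s_h = numeric(length(node1)),
                            s_t = numeric(length(node1)), alpha = 0.5,
                            nodes1 = NULL, nodes2 = NULL) {
  node1 <- as.character(node1); node2 <- as.character(node2)
  df <- data.frame(node1 = node1, node2 = node2,
                   s_h = as.numeric(s_h), s_t = as.numeric(s_t),
                   score = pair_score(s_h, s_t, alpha),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(paste(node1, node2, sep = "\r"))) {
    stop("duplicate candidate pairs")
  }
  attr(df, "nodes1") <- sort(unique(c(node1, nodes1)))
  attr(df, "nodes2") <- sort(unique(c(node2, nodes2)))
  attr(df, "alpha") <- alpha
  class(df) <- c("candidate_set", "data.frame")
  df
}

#' Objective score f(A) of an alignment under a candidate set
#'
#' The sum of the candidate-set scores of the matched pairs. Every matched
#' pair must be admissible.
#'
#' @param aln An `alignment` (or two-column matrix/data.frame of pairs).
#' @param cs A `candidate_set`.
#' @return The total score.
#' @export
objective <- function(aln, cs) {
  if (nrow(aln) == 0L) return(0)
  key <- paste(aln$node1, aln$node2, sep = "\r")
  idx <- match(key, paste(cs$node1, cs$node2, sep = "\r"))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("pair (", aln$node1[bad], ", ", aln$node2[bad], ") is not in the candidate set")
  }
  sum(cs$score[idx])
}

#' Greedy initial alignment
#'
#' Repeatedly takes the highest-scoring admissible pair whose two endpoints
#' are both still unmatched; ties are broken by lexicographic node-id order
#' (`node1`, then `node2`), which makes the seed deterministic.
#'
#' @param cs A `candidate_set`.
#' @return An `alignment`.
#' @export
initial_alignment <- function(cs) {
  ord <- order(-cs$score, cs$node1, cs$node2)
  used1 <- character(0); used2 <- character(0)
  take <- logical(nrow(cs))
  for (r in ord) {
    if (!(cs$node1[r] %in% used1) && !(cs$node2[r] %in% used2)) {
      take[r] <- TRUE
      used1 <- c(used1, cs$node1[r])
      used2 <- c(used2, cs$node2[r])
    }
  }
  sel <- cs[take, , drop = FALSE]
  alignment(sel$node1, sel$node2, s_h = sel$s_h, s_t = sel$s_t,
            alpha = attr(cs, "alpha"))
}

#' Simulated-annealing schedule parameters
#'
#' @param t0 Initial temperature (> 0).
#' @param cooling Geometric cooling factor in (0, 1) applied per temperature
#'   level.
#' @param iters_per_temp Proposals per temperature level; default
#'   `200 * max(|V1|, |V2|)` (resolved at run time when `NULL`).
#' @param min_temp Final temperature; the run stops once the temperature
#'   drops below it.
#' @param seed Integer seed for the annealer's random-number stream.
#' @return List of class `sa_params`.
#' @export
sa_params <- function(t0 = 1.0, cooling = 0.95, iters_per_temp = NULL,
                      min_temp = 1e-4, seed = 1L) {
  stopifnot(t0 > 0, cooling > 0, cooling < 1, min_temp > 0)
  structure(list(t0 = t0, cooling = cooling, iters_per_temp = iters_per_temp,
                 min_temp = min_temp, seed = as.integer(seed)),
            class = "sa_params")
}

#' Optimize a one-to-one alignment by simulated annealing
#'
#' Starts from the greedy seed of [initial_alignment()] and explores the
#' space of one-to-one match sets with two move types: swapping the partners
#' of two matched pairs (probability 1/2, when both swapped pairs are
#' admissible), or reassigning a single node to a random admissible
#' unmatched partner / unmatching it. A proposal with score change `delta`
#' is always accepted when `delta >= 0` and with probability
#' `exp(delta / T)` otherwise. The best match set encountered is returned,
#' so the result's objective is never below the greedy seed's. Runs are
#' reproducible given `params$seed`.
#'
#' @param cs A `candidate_set`.
#' @param params An [sa_params()] schedule.
#' @return An `alignment` (with attribute `objective` equal to its summed
#'   pair scores).
#' @export
anneal <- function(cs, params = sa_params()) {
  nodes1 <- attr(cs, "nodes1"); nodes2 <- attr(cs, "nodes2")
  n1 <- length(nodes1); n2 <- length(nodes2)
  if (nrow(cs) == 0L) stop("empty candidate set")
  S <- matrix(NA_real_, n1, n2, dimnames = list(nodes1, nodes2))
  S[cbind(match(cs$node1, nodes1), match(cs$node2, nodes2))] <- cs$score
  init <- initial_alignment(cs)
  init_vec <- rep(-1L, n1)
  init_vec[match(init$node1, nodes1)] <- match(init$node2, nodes2) - 1L
  iters <- params$iters_per_temp
  if (is.null(iters)) iters <- 200L * max(n1, n2)
  res <- sa_align_cpp(S, init_vec, params$t0, params$cooling,
                      as.integer(iters), params$min_temp, params$seed)
  match1 <- res$match + 1L            # 1-based, 0 -> unmatched
  sel1 <- which(match1 > 0L)
  key <- paste(nodes1[sel1], nodes2[match1[sel1]], sep = "\r")
  idx <- match(key, paste(cs$node1, cs$node2, sep = "\r"))
  alignment(nodes1[sel1], nodes2[match1[sel1]],
            s_h = cs$s_h[idx], s_t = cs$s_t[idx], alpha = attr(cs, "alpha"))
}

#' End-to-end pairwise alignment of two dynamic networks
#'
#' Computes feature sequences and the cross-network DTW similarity matrix,
#' normalizes homology scores when a table is supplied, assembles the
#' candidate set, and optimizes the match set by simulated annealing.
#'
#' @param dn1,dn2 `dynamic_network` objects.
#' @param homology Optional `homology_table` (already e-value-filtered).
#' @param alpha Weight on the sequence component (in [0, 1]).
#' @param candidates Candidate admission policy: `"auto"` uses the homology
#'   candidate set when a table is supplied and the full cross product
#'   otherwise; `"all"` and `"homologs"` force the respective policy.
#' @param params An [sa_params()] schedule.
#' @param dtw_normalize Path-length-normalize the DTW distance before the
#'   Gaussian transform (see [dtw_similarity()]).
#' @param score_mode Raw sequence score, see [raw_score()].
#' @return An `alignment`; attribute `objective` holds f(A).
#' @export
align_dynamic_networks <- function(dn1, dn2, homology = NULL, alpha = 0.5,
                                   candidates = c("auto", "all", "homologs"),
                                   params = sa_params(),
                                   dtw_normalize = FALSE,
                                   score_mode = "neglog_evalue") {
  candidates <- match.arg(candidates)
  policy <- switch(candidates,
                   auto = if (is.null(homology)) "all" else "homologs",
                   candidates)
  sh <- if (is.null(homology)) NULL else normalize_scores(homology, mode = score_mode)
  restrict <- NULL
  if (policy == "homologs") {
    if (is.null(sh)) stop("candidate policy 'homologs' requires a homology table")
    restrict <- cbind(sh$query, sh$subject)
  }
  sm <- similarity_matrix(dn1, dn2, candidates = restrict,
                          normalize = dtw_normalize)
  cs <- candidate_set(sm, homology = sh, alpha = alpha, policy = policy)
  anneal(cs, params)
}
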