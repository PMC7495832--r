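# Normalization of raw sequence-homology scores into s_h in [0, 1] over the
# filtered candidate set.

#' Raw sequence score of a homolog pair
#'
#' Either `-log10(e-value)` (mode `"neglog_evalue"`, the default) or the
#' BLAST bit-score (mode `"bitscore"`). An e-value reported as 0 (BLAST
#' underflow) is floored at `evalue_floor` before taking the log.
#'
#' @param evalue,bitscore Numeric vectors (parallel).
#' @param mode `"neglog_evalue"` or `"bitscore"`.
#' @param evalue_floor Positive floor substituted for zero e-values.
#' @return Numeric vector of raw scores (epsilon).
#' @export
raw_score <- function(evalue, bitscore, mode = c("neglog_evalue", "bitscore"),
                      evalue_floor = 1e-180) {
  mode <- match.arg(mode)
  if (mode == "bitscore") return(as.numeric(bitscore))
  ev <- pmax(as.numeric(evalue), evalue_floor)
  -log10(ev)
}

#' Normalize homolog scores to sequence similarities in [0, 1]
#'
#' Linearly rescales the raw scores epsilon over the candidate set so that
#' the weakest pair gets 0 and the strongest gets 1:
#' `s_h = (eps - eps_min) / (eps_max - eps_min)`, where the range is taken
#' globally over the whole table. If all candidates share one raw score the
#' rescaling is degenerate (0/0) and every pair is assigned `s_h = 1` — all
#' candidates are then equally, maximally supported.
#'
#' @param ht A `homology_table` (the filtered candidate set; must be
#'   non-empty).
#' @param mode,evalue_floor Passed to [raw_score()].
#' @return A data.frame with columns `query`, `subject`, `epsilon`, `s_h`.
#' @export
normalize_scores <- function(ht, mode = c("neglog_evalue", "bitscore"),
                             evalue_floor = 1e-180) {
  mode <- match.arg(mode)
  if (nrow(ht) == 0L) stop("empty homology table: nothing to normalize")
  eps <- raw_score(ht$evalue, ht$bitscore, mode = mode, evalue_floor = evalue_floor)
  delta <- max(eps) - min(eps)
  s_h <- if (delta == 0) rep(1, length(eps)) else (eps - min(eps)) / delta
  data.frame(query = ht$query, subject = ht$subject,
             epsilon = eps, s_h = s_h, stringsAsFactors = FALSE)
}
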