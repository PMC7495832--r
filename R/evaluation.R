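# Classification evaluation of alignment scores (precision-recall and ROC
# threshold sweeps, AUPR/AUROC, F-scores) and node correctness against a
# ground-truth mapping.

#' Precision-recall curve from labeled scores
#'
#' Sweeps the threshold rho over `{0}` and every distinct observed score;
#' an item is classified positive iff its score is strictly greater than
#' rho. Precision at a threshold with no positive classifications is taken
#' as 1 (the empty-prediction limit).
#'
#' @param score Numeric scores (alignment scores; assumed >= 0 so that the
#'   rho = 0 endpoint classifies everything positive).
#' @param label Logical (or 0/1) true-class labels; at least one positive
#'   is required.
#' @return data.frame with columns `threshold`, `recall`, `precision`,
#'   ordered by ascending threshold (descending recall).
#' @export
pr_curve <- function(score, label) {
  sw <- sweep_thresholds(score, label)
  data.frame(threshold = sw$threshold, recall = sw$tpr,
             precision = ifelse(sw$tp + sw$fp == 0, 1, sw$tp / (sw$tp + sw$fp)))
}

sweep_thresholds <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), !anyNA(score), !anyNA(label))
  if (!any(label)) stop("at least one positive label is required")
  if (!any(!label)) stop("at least one negative label is required")
  thr <- sort(unique(c(0, score)))
  n_pos <- sum(label); n_neg <- sum(!label)
  tp <- vapply(thr, function(t) sum(score > t & label), 0)
  fp <- vapply(thr, function(t) sum(score > t & !label), 0)
  list(threshold = thr, tp = tp, fp = fp,
       tpr = tp / n_pos, fpr = fp / n_neg)
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration of precision over recall, following the sweep
#' from the highest threshold (recall 0) down to threshold 0 (recall 1);
#' points that tie in recall (the precision dropping while recall stays
#' put) contribute zero width.
#'
#' @param curve Output of [pr_curve()].
#' @return Area in [0, 1].
#' @export
aupr <- function(curve) {
  ord <- order(-curve$threshold)
  r <- curve$recall[ord]; p <- curve$precision[ord]
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' F-score: harmonic mean of precision and recall
#'
#' @param precision,recall Numeric (vectors) in [0, 1].
#' @return `2 * precision * recall / (precision + recall)`, with 0 where
#'   both are 0.
#' @export
f_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' F-score at the precision-recall crossing, and the maximum F-score
#'
#' `f_max` is the maximum of [f_score()] over the curve points. `f_cross`
#' is the F-score at the threshold where precision equals recall; when no
#' curve point attains exact equality, the crossing is located by linear
#' interpolation (in the threshold) between the two adjacent points
#' bracketing the sign change of precision - recall, and if the sign never
#' changes the point minimizing |precision - recall| is used.
#'
#' @param curve Output of [pr_curve()].
#' @return Named list with elements `f_cross` and `f_max`.
#' @export
f_cross_and_max <- function(curve) {
  p <- curve$precision; r <- curve$recall
  f <- f_score(p, r)
  d <- p - r
  exact <- which(d == 0)
  if (length(exact) > 0L) {
    f_cross <- f[exact[1L]]
  } else {
    s <- which(d[-1L] * d[-length(d)] < 0)
    if (length(s) > 0L) {
      i <- s[1L]
      t <- d[i] / (d[i] - d[i + 1L])
      pc <- p[i] + t * (p[i + 1L] - p[i])
      rc <- r[i] + t * (r[i + 1L] - r[i])
      f_cross <- f_score(pc, rc)
    } else {
      f_cross <- f[which.min(abs(d))]
    }
  }
  list(f_cross = f_cross, f_max = max(f))
}

#' ROC curve from labeled scores
#'
#' Same threshold sweep as [pr_curve()] (positive iff score strictly above
#' rho): true-positive rate against false-positive rate.
#'
#' @inheritParams pr_curve
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(score, label) {
  sw <- sweep_thresholds(score, label)
  data.frame(threshold = sw$threshold, fpr = sw$fpr, tpr = sw$tpr)
}

#' Area under the ROC curve
#'
#' Trapezoidal area of the [roc_curve()] sweep. For strictly positive
#' scores this equals the rank statistic
#' `P(score_pos > score_neg) + 0.5 * P(tie)`.
#'
#' @inheritParams pr_curve
#' @return Area in [0, 1].
#' @export
auroc <- function(score, label) {
  rc <- roc_curve(score, label)
  ord <- order(rc$fpr, rc$tpr)
  x <- rc$fpr[ord]; y <- rc$tpr[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Node correctness of an alignment against a ground-truth mapping
#'
#' The fraction of correctly aligned node pairs: `N_correct / N_all`, where
#' `N_correct` counts aligned pairs that occur in the reference mapping.
#' By default `N_all` is the number of pairs the aligner reported (a
#' precision over the output); `denominator = "truth"` divides by the size
#' of the reference mapping instead (a recall).
#'
#' @param aln An `alignment` (or data.frame with `node1`, `node2`).
#' @param truth Named character vector (names = network-1 nodes, values =
#'   true partners) or two-column matrix.
#' @param denominator `"alignment"` (default) or `"truth"`.
#' @return Node correctness in [0, 1]; 0 for an empty alignment.
#' @export
node_correctness <- function(aln, truth, denominator = c("alignment", "truth")) {
  denominator <- match.arg(denominator)
  if (is.matrix(truth)) truth <- stats::setNames(truth[, 2L], truth[, 1L])
  if (nrow(aln) == 0L) return(0)
  n_correct <- sum(paste(aln$node1, aln$node2, sep = "\r") %in%
                     paste(names(truth), unname(truth), sep = "\r"))
  n_all <- if (denominator == "alignment") nrow(aln) else length(truth)
  n_correct / n_all
}
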