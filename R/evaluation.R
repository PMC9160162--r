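# Detection-quality evaluation: IoU > 0.5 true-positive rule, equal-count
# score bins, precision/recall/F1 per threshold, and average precision as
# the trapezoidal area under the precision-recall curve extrapolated to
# (recall 0, precision 1) but never beyond the maximum observed recall.

#' Match predictions to ground truth
#'
#' Greedy one-to-one matching in descending prediction-score order: each
#' prediction claims its best still-unmatched ground-truth mask and is a
#' true positive iff that IoU is strictly greater than `iou_thr`; each
#' ground truth can be matched at most once. Every prediction ends up in
#' exactly one of tp/fp.
#'
#' @param preds List of `eq_detection` (with scores).
#' @param gts List of ground-truth `eq_mask`.
#' @param iou_thr True-positive bound (default 0.5; strict `>`).
#' @return List of class `"eq_match"`: `tp` (data.frame `pred`, `gt`,
#'   `iou`, `score`), `fp` (indices into `preds`), `fn` (indices into
#'   `gts`), `order` (prediction indices in the matching order).
#' @export
match_detections <- function(preds, gts, iou_thr = 0.5) {
  n_p <- length(preds); n_g <- length(gts)
  scores <- vapply(preds, `[[`, numeric(1), "score")
  ord <- order(scores, decreasing = TRUE)
  gt_boxes <- lapply(gts, mask_bbox)
  gt_taken <- rep(FALSE, n_g)
  tp <- list(); fp <- integer(0)
  for (i in ord) {
    pb <- preds[[i]]$bbox
    best_iou <- 0; best_gt <- NA_integer_
    for (j in seq_len(n_g)) {
      if (gt_taken[j]) next
      if (!bbox_intersects(pb, gt_boxes[[j]])) next
      v <- iou(preds[[i]]$mask, gts[[j]])
      if (v > best_iou) { best_iou <- v; best_gt <- j }
    }
    if (!is.na(best_gt) && best_iou > iou_thr) {
      gt_taken[best_gt] <- TRUE
      tp[[length(tp) + 1L]] <- data.frame(pred = i, gt = best_gt,
                                          iou = best_iou, score = scores[i])
    } else {
      fp <- c(fp, i)
    }
  }
  tp_df <- if (length(tp)) do.call(rbind, tp) else
    data.frame(pred = integer(0), gt = integer(0), iou = numeric(0),
               score = numeric(0))
  structure(list(tp = tp_df, fp = fp, fn = which(!gt_taken), order = ord),
            class = "eq_match")
}

#' Precision, recall and F1 from a match result
#'
#' `precision = TP / (TP + FP)`, `recall = TP / n_gt`, and F1 is the
#' harmonic mean `2pr/(p + r)` (0 when `p + r = 0`). With zero predictions
#' precision is undefined and reported as 1 by convention, flagged via the
#' `"degenerate"` attribute.
#'
#' @param match An `eq_match` (or a list with `tp` rows and `fp` indices).
#' @param n_gt Number of ground-truth objects (`> 0`).
#' @return Named numeric `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(match, n_gt) {
  stopifnot(n_gt > 0)
  tp <- nrow(match$tp); fp <- length(match$fp)
  degenerate <- (tp + fp) == 0L
  p <- if (degenerate) 1 else tp / (tp + fp)
  r <- tp / n_gt
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  out <- c(precision = p, recall = r, f1 = f1)
  attr(out, "degenerate") <- degenerate
  out
}

equal_count_thresholds <- function(scores, n_bins) {
  s <- sort(scores)
  n <- length(s)
  if (length(unique(s)) < n_bins) return(sort(unique(s)))
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  unique(s[cumsum(sizes)])
}

#' Precision-recall curve over equal-count score bins
#'
#' Prediction scores are ordered from smallest to largest and split into
#' `n_bins` bins each containing the same number of predictions (counts
#' differing by at most one when the total is not divisible); the maximum
#' score of each bin defines a threshold. At each threshold t the subset of
#' predictions with score `>= t` is evaluated for precision, recall and F1
#' against the ground truth. When there are fewer distinct scores than
#' bins, one threshold per distinct score is used instead.
#'
#' @param preds List of `eq_detection` (at least one).
#' @param gts List of ground-truth `eq_mask`.
#' @param n_bins Number of equal-count bins (default 100).
#' @param iou_thr True-positive IoU bound (default 0.5).
#' @return An object of class `"eq_curve"`: data.frame-compatible list with
#'   `thresholds` (ascending), `precision`, `recall`, `f1`, plus `ap`
#'   (see [average_precision()]) and `n_gt`.
#' @export
pr_curve <- function(preds, gts, n_bins = 100L, iou_thr = 0.5) {
  stopifnot(length(preds) >= 1L, length(gts) >= 1L)
  match <- match_detections(preds, gts, iou_thr)
  scores <- vapply(preds, `[[`, numeric(1), "score")
  thresholds <- equal_count_thresholds(scores, n_bins)
  # Greedy matching of the score>=t subset equals the full matching
  # restricted to that subset (the subset is a prefix of the match order),
  # so one matching pass serves every threshold.
  tp_scores <- match$tp$score
  n_gt <- length(gts)
  p <- r <- f1 <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    t <- thresholds[k]
    tp <- sum(tp_scores >= t)
    n_pred <- sum(scores >= t)
    p[k] <- if (n_pred == 0L) 1 else tp / n_pred
    r[k] <- tp / n_gt
    f1[k] <- if (p[k] + r[k] == 0) 0 else 2 * p[k] * r[k] / (p[k] + r[k])
  }
  curve <- structure(list(thresholds = thresholds, precision = p,
                          recall = r, f1 = f1, n_gt = n_gt),
                     class = "eq_curve")
  curve$ap <- average_precision(curve)
  curve
}

#' Average precision of a precision-recall curve
#'
#' Trapezoidal area under the (recall, precision) points sorted by recall,
#' prepended with the extrapolated point (recall 0, precision 1). The curve
#' is not extended beyond the maximum observed recall (no extrapolation
#' toward recall 1).
#'
#' @param curve An `eq_curve` (or list with `recall` and `precision`).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(curve) {
  stopifnot(length(curve$recall) >= 1L)
  ord <- order(curve$recall, curve$precision)
  r <- c(0, curve$recall[ord])
  p <- c(1, curve$precision[ord])
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Threshold maximizing F1
#'
#' @param curve An `eq_curve`.
#' @return Named numeric `c(threshold, f1)`; ties broken toward the
#'   smallest threshold.
#' @export
best_threshold <- function(curve) {
  stopifnot(length(curve$thresholds) >= 1L)
  k <- which.max(curve$f1)   # thresholds ascend; which.max takes the first
  c(threshold = curve$thresholds[k], f1 = curve$f1[k])
}

#' @export
print.eq_curve <- function(x, ...) {
  bt <- best_threshold(x)
  cat(sprintf("<PR curve: %d thresholds, AP %.3f, best F1 %.3f at t=%.3f>\n",
              length(x$thresholds), x$ap, bt["f1"], bt["threshold"]))
  invisible(x)
}

#' Curve as a data frame
#' @param x An `eq_curve`.
#' @param ... Unused.
#' @return data.frame with threshold, precision, recall, f1.
#' @export
as.data.frame.eq_curve <- function(x, ...) {
  data.frame(threshold = x$thresholds, precision = x$precision,
             recall = x$recall, f1 = x$f1)
}
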