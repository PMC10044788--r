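# Detection and tracking metrics: IoU, average precision and mAP over IoU
# thresholds 0.5-0.9, MOTA, the identity-level ID correct rate (ICR), the
# centroid-based track scorer producing both tallies, and the "N-1"
# chi-squared proportion comparison.

#' Intersection over union of two boxes
#'
#' Boxes are half-open \code{c(x0, y0, x1, y1)} with \code{x1 > x0},
#' \code{y1 > y0}; disjoint boxes score 0.
#'
#' @param a,b numeric boxes.
#' @return IoU in [0, 1].
#' @export
iou <- function(a, b) {
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2])
    stop("degenerate box")
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# TP/FP flags of detections (sorted by descending confidence) against truth
# at one IoU threshold, greedy highest-IoU matching per detection, one
# detection per ground-truth box.
matchDetections <- function(detections, truth, iouThreshold) {
  det <- detections[order(-detections$conf), , drop = FALSE]
  used <- logical(nrow(truth))
  tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    cand <- which(!used & truth$frame == det$frame[i])
    if (length(cand) == 0) next
    ious <- vapply(cand, function(g)
      iou(as.numeric(det[i, c("x0", "y0", "x1", "y1")]),
          as.numeric(truth[g, c("x0", "y0", "x1", "y1")])), 1.0)
    best <- which.max(ious)
    if (ious[best] >= iouThreshold) {
      tp[i] <- TRUE
      used[cand[best]] <- TRUE
    }
  }
  list(tp = tp, conf = det$conf, n_truth = nrow(truth))
}

#' Average precision at one IoU threshold
#'
#' Builds the precision-recall curve over descending confidence with greedy
#' highest-IoU matching (one detection per ground-truth box) and integrates
#' it by all-points interpolation.
#'
#' @param detections data.frame frame, x0, y0, x1, y1, conf.
#' @param truth data.frame frame, x0, y0, x1, y1.
#' @param iouThreshold matching threshold.
#' @return AP in [0, 1].
#' @export
averagePrecision <- function(detections, truth, iouThreshold = 0.5) {
  if (nrow(truth) == 0) stop("average precision undefined with no ground truth")
  if (nrow(detections) == 0) return(0)
  m <- matchDetections(detections, truth, iouThreshold)
  tp_cum <- cumsum(m$tp)
  fp_cum <- cumsum(!m$tp)
  recall <- tp_cum / m$n_truth
  precision <- tp_cum / (tp_cum + fp_cum)
  # all-points interpolation: precision envelope integrated over recall
  r <- c(0, recall)
  p <- c(1, precision)
  for (i in rev(seq_len(length(p) - 1))) p[i] <- max(p[i], p[i + 1])
  sum(diff(r) * p[-1])
}

#' Mean average precision over IoU thresholds
#'
#' \code{mAP@0.5:0.9} is the mean of AP at thresholds 0.5 to 0.9 in steps
#' of 0.1 (five thresholds).
#'
#' @inheritParams averagePrecision
#' @param thresholds IoU thresholds to average over.
#' @return mAP in [0, 1].
#' @export
mapMetric <- function(detections, truth, thresholds = seq(0.5, 0.9, by = 0.1)) {
  mean(vapply(thresholds, function(t)
    averagePrecision(detections, truth, t), 1.0))
}

#' Error counts container
#'
#' @param miss,switch,drift identity-level error tallies (summed over
#'   frames).
#' @param fn,fp,idsw CLEAR-style tallies (false negatives, false positives,
#'   identity switches).
#' @param gt total ground-truth count, frames x declared identities.
#' @return named list of counts.
#' @export
errorCounts <- function(miss = 0, switch = 0, drift = 0,
                        fn = 0, fp = 0, idsw = 0, gt) {
  counts <- list(miss = miss, switch = switch, drift = drift,
                 fn = fn, fp = fp, idsw = idsw, gt = gt)
  if (any(unlist(counts) < 0)) stop("counts must be nonnegative")
  counts
}

#' Multiple object tracking accuracy (MOTA)
#'
#' \code{1 - (FN + FP + IDSW) / GT}; may be negative.
#'
#' @param counts from \code{\link{errorCounts}} or
#'   \code{\link{scoreTracks}}.
#' @return MOTA value (at most 1).
#' @export
mota <- function(counts) {
  if (is.null(counts$gt) || counts$gt <= 0) stop("gt must be positive")
  1 - (counts$fn + counts$fp + counts$idsw) / counts$gt
}

#' Identity correct rate (ICR)
#'
#' \code{1 - (Miss + Switch + Drift) / GT}: the fraction of individual
#' images whose identity was tracked correctly, where GT is the number of
#' frames times the declared number of identities.
#'
#' @param counts from \code{\link{errorCounts}} or
#'   \code{\link{scoreTracks}}.
#' @return ICR value (at most 1).
#' @examples
#' icr(errorCounts(miss = 0, switch = 0, drift = 135, gt = 16000 * 2)) # 0.9958
#' @export
icr <- function(counts) {
  if (is.null(counts$gt) || counts$gt <= 0) stop("gt must be positive")
  1 - (counts$miss + counts$switch + counts$drift) / counts$gt
}

#' Score predicted tracks against ground truth
#'
#' Per frame, predictions are matched to ground-truth positions by nearest
#' centroid within \code{matchRadius} (globally optimal matching). Each
#' predicted identity's mapping to a true identity is established by
#' majority vote over the first \code{window} frames in which it is matched
#' and then frozen; afterwards, a match under a different true identity
#' counts as a switch, a match farther than \code{driftRadius} (but within
#' \code{matchRadius}, under the consistent mapping) counts as a drift, and
#' an unmatched true identity counts as a miss. CLEAR-style FN/FP/IDSW
#' tallies are computed independently per standard MOT semantics (IDSW: a
#' matched true identity changes its associated predicted identity).
#'
#' @param pred,truth track data.frames (frame, id, x, y).
#' @param matchRadius association gate, pixels.
#' @param driftRadius drift threshold, pixels.
#' @param window mapping-vote window, frames.
#' @return counts list (as \code{\link{errorCounts}}) with
#'   \code{gt = frames x identities}.
#' @export
scoreTracks <- function(pred, truth, matchRadius = 20, driftRadius = 6,
                        window = 30L) {
  frames <- sort(unique(truth$frame))
  ids <- sort(unique(truth$id))
  per_frame <- tapply(truth$id, truth$frame, function(x) sort(unique(x)))
  if (!all(vapply(per_frame, function(x) identical(as.integer(x),
                                                   as.integer(ids)), TRUE)))
    stop("truth identity sets inconsistent across frames")
  miss <- switch_ <- drift <- fn <- fp <- idsw <- 0
  votes <- list()          # pred id -> named tally of truth ids (early frames)
  frozen <- list()         # pred id -> mapped truth id
  last_pred_of_truth <- list()
  for (fr in frames) {
    tr <- truth[truth$frame == fr, , drop = FALSE]
    pr <- pred[pred$frame == fr, , drop = FALSE]
    matched_t <- rep(NA_integer_, nrow(tr))   # index into pr
    if (nrow(pr) > 0) {
      D <- outer(seq_len(nrow(tr)), seq_len(nrow(pr)),
                 Vectorize(function(i, j)
                   sqrt((tr$x[i] - pr$x[j])^2 + (tr$y[i] - pr$y[j])^2)))
      Dg <- ifelse(D <= matchRadius, D, 1e6)
      if (nrow(tr) <= nrow(pr)) {
        as_ <- solveAssignment(Dg)
        for (i in seq_len(nrow(tr)))
          if (Dg[i, as_[i]] < 1e6) matched_t[i] <- as_[i]
      } else {
        as_ <- solveAssignment(t(Dg))
        for (j in seq_len(nrow(pr)))
          if (Dg[as_[j], j] < 1e6) matched_t[as_[j]] <- j
      }
    }
    fn <- fn + sum(is.na(matched_t))
    fp <- fp + nrow(pr) - sum(!is.na(matched_t))
    miss <- miss + sum(is.na(matched_t))
    for (i in seq_len(nrow(tr))) {
      j <- matched_t[i]
      if (is.na(j)) next
      tid <- as.character(tr$id[i])
      pid_ <- as.character(pr$id[j])
      # CLEAR IDSW: the predicted identity associated with this true
      # identity changed since its last match
      if (!is.null(last_pred_of_truth[[tid]]) &&
          last_pred_of_truth[[tid]] != pid_) idsw <- idsw + 1
      last_pred_of_truth[[tid]] <- pid_
      # identity-level mapping: vote during the first `window` matches of
      # this predicted identity, then freeze
      if (is.null(frozen[[pid_]])) {
        v <- votes[[pid_]]
        if (is.null(v)) v <- integer()
        v[tid] <- if (is.na(v[tid])) 1L else v[tid] + 1L
        votes[[pid_]] <- v
        if (sum(v) >= window) frozen[[pid_]] <- names(which.max(v))
        mapped <- names(which.max(v))
      } else {
        mapped <- frozen[[pid_]]
      }
      if (mapped != tid) {
        switch_ <- switch_ + 1
      } else if (D[i, j] > driftRadius) {
        drift <- drift + 1
      }
    }
  }
  errorCounts(miss = miss, switch = switch_, drift = drift,
              fn = fn, fp = fp, idsw = idsw,
              gt = length(frames) * length(ids))
}

#' "N-1" chi-squared test of two proportions
#'
#' The Pearson chi-squared statistic of the 2x2 table scaled by
#' \code{(N - 1) / N} with \code{N = nA + nB}; two-sided p-value from the
#' chi-squared distribution with one degree of freedom.
#'
#' @param successesA,nA successes and size of sample A.
#' @param successesB,nB successes and size of sample B.
#' @return list with \code{statistic} and \code{p.value}.
#' @export
n1Chisq <- function(successesA, nA, successesB, nB) {
  if (nA <= 0 || nB <= 0) stop("sample sizes must be positive")
  if (successesA > nA || successesB > nB) stop("successes must not exceed n")
  a <- successesA; b <- nA - successesA
  c_ <- successesB; d <- nB - successesB
  N <- nA + nB
  m1 <- a + c_; m2 <- b + d
  if (m1 == 0 || m2 == 0)
    stop("degenerate table: a zero margin makes the test undefined")
  chi2 <- N * (a * d - b * c_)^2 / (nA * nB * m1 * m2)
  stat <- chi2 * (N - 1) / N
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}
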