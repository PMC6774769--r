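asMask <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("mask contains NA")
  m != 0
}

checkPair <- function(pred, truth) {
  pred <- asMask(pred); truth <- asMask(truth)
  if (!all(dim(pred) == dim(truth)))
    stop(sprintf("mask shapes differ: %dx%d vs %dx%d",
                 nrow(pred), ncol(pred), nrow(truth), ncol(truth)))
  list(pred = pred, truth = truth)
}

#' Pixel-wise confusion counts
#'
#' @param pred predicted binary mask (logical or 0/1 matrix).
#' @param truth ground-truth binary mask of the same shape.
#' @return named list TP, FP, TN, FN plus S (total skin pixels) and NS
#'   (total non-skin pixels); TP + FN = S, FP + TN = NS.
#' @export
confusionCounts <- function(pred, truth) {
  m <- checkPair(pred, truth)
  TP <- sum(m$pred & m$truth)
  FP <- sum(m$pred & !m$truth)
  FN <- sum(!m$pred & m$truth)
  TN <- sum(!m$pred & !m$truth)
  list(TP = TP, FP = FP, TN = TN, FN = FN, S = TP + FN, NS = FP + TN)
}

#' True-positive and false-positive rates
#'
#' TPR = TP / S and FPR = FP / NS for pixel-wise skin classification.
#'
#' @param counts a list from \code{\link{confusionCounts}}.
#' @return named numeric c(tpr, fpr).
#' @export
tprFpr <- function(counts) {
  if (counts$S == 0) stop("TPR undefined: ground truth has no skin pixels")
  if (counts$NS == 0) stop("FPR undefined: ground truth has no non-skin pixels")
  c(tpr = counts$TP / counts$S, fpr = counts$FP / counts$NS)
}

#' Intersection-over-union of two masks
#'
#' Pixels common to target and prediction divided by pixels present in
#' either. Two empty masks score 1 (perfect agreement on a blank frame).
#'
#' @inheritParams confusionCounts
#' @return scalar in [0, 1].
#' @export
maskIoU <- function(pred, truth) {
  m <- checkPair(pred, truth)
  un <- sum(m$pred | m$truth)
  if (un == 0) {
    message("both masks empty; IoU defined as 1")
    return(1)
  }
  sum(m$pred & m$truth) / un
}

#' Dice coefficient of two masks
#'
#' 2 |intersection| / (|target| + |prediction|); algebraically
#' 2 IoU / (1 + IoU). Two empty masks score 1.
#'
#' @inheritParams confusionCounts
#' @return scalar in [0, 1].
#' @export
maskDice <- function(pred, truth) {
  m <- checkPair(pred, truth)
  tot <- sum(m$pred) + sum(m$truth)
  if (tot == 0) {
    message("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(m$pred & m$truth) / tot
}

#' ROC sweep of a probability map against ground truth
#'
#' Thresholds the map at each value of a grid and records (FPR, TPR);
#' thresholds are applied in descending order so the curve runs from (0, 0)
#' towards (1, 1) and both coordinates are non-decreasing along it.
#'
#' @param pm probability map (numeric matrix).
#' @param truth ground-truth binary mask of the same shape.
#' @param thresholds at least two threshold values; default 101 evenly
#'   spaced values in [0, 1].
#' @return data.frame with columns threshold, fpr, tpr, ordered by
#'   descending threshold.
#' @export
rocCurve <- function(pm, truth, thresholds = seq(0, 1, length.out = 101)) {
  if (length(thresholds) < 2L) stop("need at least 2 thresholds")
  truth <- asMask(truth)
  if (!all(dim(pm) == dim(truth))) stop("map and truth shapes differ")
  thresholds <- sort(thresholds, decreasing = TRUE)
  pts <- vapply(thresholds, function(tau) {
    tprFpr(confusionCounts(pm >= tau, truth))
  }, numeric(2))
  data.frame(threshold = thresholds, fpr = pts["fpr", ], tpr = pts["tpr", ])
}

#' Full evaluation of a predicted mask
#'
#' @inheritParams confusionCounts
#' @return one-row data.frame with tpr, fpr, iou, dice and the confusion
#'   counts.
#' @export
evaluateMask <- function(pred, truth) {
  counts <- confusionCounts(pred, truth)
  rates <- tprFpr(counts)
  data.frame(tpr = rates["tpr"], fpr = rates["fpr"],
             iou = maskIoU(pred, truth), dice = maskDice(pred, truth),
             TP = counts$TP, FP = counts$FP, TN = counts$TN, FN = counts$FN,
             row.names = NULL)
}
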