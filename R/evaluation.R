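#' Pixel-level confusion counts
#'
#' Counts true/false positives/negatives between a predicted and a
#' reference burnt mask (positive class = burnt), optionally restricted to
#' a validity mask (e.g. the forest mask).
#'
#' @param pred,truth [burn_mask()] objects (or plain 0/1 matrices) on the
#'   same grid.
#' @param valid Optional 0/1 matrix or [forest_mask()]; only pixels with 1
#'   are counted. Default: all pixels.
#' @return A `confusion_counts` tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, truth, valid = NULL) {
  p <- mask_values(pred)
  t <- mask_values(truth)
  if (!all(dim(p) == dim(t))) stop("pred and truth grids do not match")
  if (inherits(pred, "burn_mask") && inherits(truth, "burn_mask") &&
      !grids_identical(pred$grid, truth$grid)) {
    stop("pred and truth must be co-registered")
  }
  if (!is.null(valid)) {
    v <- mask_values(valid) == 1
    if (!all(dim(v) == dim(p))) stop("valid mask grid does not match")
    p <- p[v]; t <- t[v]
  }
  out <- tibble::tibble(
    tp = sum(p == 1 & t == 1), fp = sum(p == 1 & t == 0),
    fn = sum(p == 0 & t == 1), tn = sum(p == 0 & t == 0)
  )
  class(out) <- c("confusion_counts", class(out))
  out
}

mask_values <- function(x) {
  if (inherits(x, "burn_mask") || inherits(x, "forest_mask")) x$mask else x
}

#' Segmentation metrics from confusion counts
#'
#' Computes precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, F1
#' `2PR/(P+R)`, accuracy `(tp+tn)/total`, burnt-class IoU `tp/(tp+fp+fn)`
#' and Dice `2tp/(2tp+fp+fn)`. With `average = "macro"`, IoU and Dice are
#' macro-averaged over the burnt and unburnt classes instead (the default
#' burnt-class form is the one consistent with the single-class
#' Dice = 2 IoU / (1 + IoU) identity).
#'
#' Degenerate 0/0 ratios are 0, except the no-positives-anywhere perfect
#' case (`tp = fp = fn = 0`) where F1, IoU and Dice are 1.
#'
#' @param counts A `confusion_counts` row ([confusion()]) or a list with
#'   `tp`, `fp`, `fn`, `tn`.
#' @param average `"burnt"` (default) or `"macro"` for IoU/Dice.
#' @return A `metrics_report` tibble with columns `precision`, `recall`,
#'   `f1`, `accuracy`, `iou`, `dice`.
#' @export
metrics_from_counts <- function(counts, average = c("burnt", "macro")) {
  average <- match.arg(average)
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn); tn <- as.numeric(counts$tn)
  total <- tp + fp + fn + tn
  stopifnot(total > 0, tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  ratio <- function(num, den, empty = 0) if (den == 0) empty else num / den
  perfect_empty <- (tp + fp + fn) == 0
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (perfect_empty) 1 else ratio(2 * precision * recall, precision + recall)
  accuracy <- (tp + tn) / total
  iou_burnt <- if (perfect_empty) 1 else ratio(tp, tp + fp + fn)
  dice_burnt <- if (perfect_empty) 1 else ratio(2 * tp, 2 * tp + fp + fn)
  if (average == "macro") {
    iou_un <- if ((tn + fp + fn) == 0) 1 else tn / (tn + fp + fn)
    dice_un <- if ((tn + fp + fn) == 0) 1 else 2 * tn / (2 * tn + fp + fn)
    iou <- (iou_burnt + iou_un) / 2
    dice <- (dice_burnt + dice_un) / 2
  } else {
    iou <- iou_burnt
    dice <- dice_burnt
  }
  out <- tibble::tibble(precision = precision, recall = recall, f1 = f1,
                        accuracy = accuracy, iou = iou, dice = dice)
  class(out) <- c("metrics_report", class(out))
  out
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR/(P+R)`; 0 when both are 0.
#'
#' @param p,r Precision and recall in `[0, 1]`.
#' @return Numeric F1.
#' @export
f1_from_precision_recall <- function(p, r) {
  stopifnot(all(p >= 0), all(p <= 1), all(r >= 0), all(r <= 1))
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

#' Dice coefficient from single-class IoU
#'
#' The single-class Dice-Jaccard identity `2 IoU / (1 + IoU)`.
#'
#' @param iou IoU in `[0, 1]`.
#' @return Numeric Dice.
#' @export
dice_from_iou <- function(iou) {
  stopifnot(all(iou >= 0), all(iou <= 1))
  2 * iou / (1 + iou)
}

# Banker's rounding of a percentage to 2 decimals (round() in R is half-even).
pct2 <- function(count, total) round(100 * count / total, 2)

#' Whole-scene pixel accounting
#'
#' Actual and predicted burnt/unburnt pixel counts and their percentages of
#' the scene total, plus the misclassified count (`fp + fn`). Percentages
#' are reported to 2 decimals (half-even rounding).
#'
#' @param pred,truth Co-registered [burn_mask()] objects (or 0/1 matrices).
#' @param valid Optional validity mask; default all pixels.
#' @return A `pixel_accounting` tibble with columns `quantity`, `pixels`,
#'   `percent`.
#' @export
pixel_report <- function(pred, truth, valid = NULL) {
  pixel_report_from_counts(confusion(pred, truth, valid))
}

#' Pixel accounting from pre-computed confusion counts
#'
#' Same report as [pixel_report()], starting from counts rather than masks —
#' useful for scenes whose confusion matrix is already tabulated.
#'
#' @param counts A `confusion_counts` row or list with `tp`, `fp`, `fn`,
#'   `tn`.
#' @return A `pixel_accounting` tibble.
#' @export
pixel_report_from_counts <- function(counts) {
  cc <- counts
  total <- cc$tp + cc$fp + cc$fn + cc$tn
  actual_burnt <- cc$tp + cc$fn
  actual_unburnt <- cc$fp + cc$tn
  pred_burnt <- cc$tp + cc$fp
  pred_unburnt <- cc$fn + cc$tn
  mis <- cc$fp + cc$fn
  out <- tibble::tibble(
    quantity = c("actual_burnt", "actual_unburnt", "predicted_burnt",
                 "predicted_unburnt", "misclassified"),
    pixels = c(actual_burnt, actual_unburnt, pred_burnt, pred_unburnt, mis),
    percent = c(pct2(actual_burnt, total), pct2(actual_unburnt, total),
                pct2(pred_burnt, total), pct2(pred_unburnt, total),
                pct2(mis, total))
  )
  attr(out, "total") <- total
  class(out) <- c("pixel_accounting", class(out))
  out
}

#' Full metric suite between predicted and reference masks
#'
#' Convenience wrapper: confusion counts, derived metrics and pixel
#' accounting in one call.
#'
#' @inheritParams confusion
#' @param average Passed to [metrics_from_counts()].
#' @return List with `counts`, `metrics`, `accounting`.
#' @export
evaluate_masks <- function(pred, truth, valid = NULL,
                           average = c("burnt", "macro")) {
  cc <- confusion(pred, truth, valid)
  list(counts = cc,
       metrics = metrics_from_counts(cc, match.arg(average)),
       accounting = pixel_report(pred, truth, valid))
}

#' Area under the ROC curve for a burnt-probability map
#'
#' Rank-based (Mann-Whitney) AUC of the predicted burnt-class probability
#' against the reference mask. Only meaningful for probability maps; argmax
#' masks should be scored with [metrics_from_counts()].
#'
#' @param probs Numeric matrix of burnt-class probabilities.
#' @param truth [burn_mask()] or 0/1 matrix.
#' @param valid Optional validity mask.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
roc_auc <- function(probs, truth, valid = NULL) {
  t <- as.vector(mask_values(truth))
  p <- as.vector(probs)
  if (!is.null(valid)) {
    v <- as.vector(mask_values(valid)) == 1
    t <- t[v]; p <- p[v]
  }
  n1 <- sum(t == 1); n0 <- sum(t == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[t == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
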