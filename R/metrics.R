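# Segmentation evaluation: confusion-matrix accumulation and mIoU,
# precision, recall, F1 and Dice, reported as percentages.

#' Create an empty metric accumulator
#'
#' @param n_classes number of classes including background.
#' @return a `metric_accumulator` with a zero `n_classes x n_classes`
#'   confusion matrix (rows = ground truth, columns = prediction) and an
#'   ignored-pixel count.
#' @export
metric_accumulator <- function(n_classes) {
  structure(list(confusion = matrix(0, n_classes, n_classes),
                 ignored = 0, n_classes = as.integer(n_classes)),
            class = "metric_accumulator")
}

#' Accumulate a prediction/ground-truth pair
#'
#' Adds per-pixel counts to the confusion matrix; ground-truth pixels with
#' the 255 ignore sentinel are skipped (and counted in `ignored`).
#' Accumulation is associative: accumulating a batch equals summing the
#' accumulators of its parts.
#'
#' @param acc a [metric_accumulator()].
#' @param pred integer label array (no 255 allowed).
#' @param gt integer label array of the same shape; 255 = ignore.
#' @return the updated accumulator.
#' @export
accumulate <- function(acc, pred, gt) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt))
    stop("prediction and ground truth shapes differ")
  p <- as.integer(pred); g <- as.integer(gt)
  if (any(p == IGNORE_LABEL)) stop("predictions must not contain 255")
  C <- acc$n_classes
  keep <- g != IGNORE_LABEL
  if (any(p[keep] < 0 | p[keep] >= C) || any(g[keep] < 0 | g[keep] >= C))
    stop("labels outside 0..", C - 1L)
  acc$ignored <- acc$ignored + sum(!keep)
  if (any(keep)) {
    tab <- tabulate(g[keep] * C + p[keep] + 1L, nbins = C * C)
    acc$confusion <- acc$confusion + matrix(tab, C, C, byrow = TRUE)
  }
  acc
}

#' Compute segmentation metrics from an accumulator
#'
#' Per-class `IoU_c = TP / (TP + FP + FN)` and
#' `Dice_c = 2 TP / (2 TP + FP + FN)` (algebraically identical to the
#' per-class F1). mIoU averages IoU over the classes present in the ground
#' truth. Precision, recall, F1 and Dice are macro-averaged over the
#' foreground classes present in ground truth or prediction (the background
#' class and classes absent from both are excluded). All values are
#' percentages in `[0, 100]`.
#'
#' @param acc a [metric_accumulator()] with at least one valid pixel.
#' @param foreground_only if `FALSE`, macro averages include background.
#' @return list with `miou`, `precision`, `recall`, `f1`, `dice`, and a
#'   `per_class` data frame.
#' @export
compute_metrics <- function(acc, foreground_only = TRUE) {
  cm <- acc$confusion
  if (sum(cm) == 0) stop("no valid pixels accumulated")
  C <- acc$n_classes
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  iou <- ifelse(tp + fp + fn > 0, tp / (tp + fp + fn), NA_real_)
  dice <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), NA_real_)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  in_gt <- rowSums(cm) > 0
  present <- in_gt | colSums(cm) > 0
  macro_set <- if (foreground_only) which(present)[which(present) > 1] else which(present)
  if (!length(macro_set)) macro_set <- which(present)
  per_class <- data.frame(class = seq_len(C) - 1L, iou = 100 * iou,
                          precision = 100 * prec, recall = 100 * rec,
                          f1 = 100 * f1, dice = 100 * dice)
  list(miou = 100 * mean(iou[in_gt], na.rm = TRUE),
       precision = 100 * mean(prec[macro_set]),
       recall = 100 * mean(rec[macro_set]),
       f1 = 100 * mean(f1[macro_set]),
       dice = 100 * mean(dice[macro_set], na.rm = TRUE),
       per_class = per_class)
}
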