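## Evaluation: pixel confusion counts and the standard segmentation
## metrics. Counts are pooled over a test set by default (per-image metrics
## are available by calling computeMetrics per sample).

#' Pixel confusion counts
#'
#' Tallies true/false positives/negatives between a thresholded prediction
#' and the binary ground truth; with a field-of-view mask, only pixels
#' inside it are counted.
#'
#' @param predicted binary prediction (matrix/array of 0/1).
#' @param labels binary ground truth, same shape.
#' @param fov optional binary mask restricting evaluation.
#' @return named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusionCounts <- function(predicted, labels, fov = NULL) {
  if (!identical(dim(predicted), dim(labels)) ||
      length(predicted) != length(labels))
    stop("shape mismatch between predictions and labels")
  p <- as.numeric(predicted)
  y <- as.numeric(labels)
  if (!all(p %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("confusion counts need binary inputs")
  if (!is.null(fov)) {
    keep <- as.logical(fov)
    p <- p[keep]
    y <- y[keep]
  }
  c(TP = sum(p == 1 & y == 1), FP = sum(p == 1 & y == 0),
    TN = sum(p == 0 & y == 0), FN = sum(p == 0 & y == 1))
}

#' Segmentation metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, F1 `2TP/(2TP+FP+FN)`, and mean IoU — the average of the
#' vessel IoU `TP/(TP+FP+FN)` and the background IoU `TN/(TN+FN+FP)`.
#' Degenerate denominators yield 0 with a warning.
#'
#' @param counts named vector with `TP`, `FP`, `TN`, `FN` (as from
#'   [confusionCounts()]).
#' @return named numeric vector `c(Acc, SE, SP, F1, MIoU)`, each in
#'   `[0, 1]`.
#' @examples
#' computeMetrics(c(TP = 8, FN = 2, FP = 5, TN = 85))
#' @export
computeMetrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
  total <- tp + fp + tn + fn
  if (total <= 0) stop("no pixels to evaluate")
  sdiv <- function(num, den) {
    if (den == 0) {
      warning("degenerate denominator; metric set to 0")
      return(0)
    }
    num / den
  }
  c(Acc = sdiv(tp + tn, total),
    SE = sdiv(tp, tp + fn),
    SP = sdiv(tn, tn + fp),
    F1 = sdiv(2 * tp, 2 * tp + fp + fn),
    MIoU = 0.5 * (sdiv(tp, tp + fp + fn) + sdiv(tn, tn + fn + fp)))
}
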