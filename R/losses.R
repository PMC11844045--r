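## Training objective: soft Dice loss plus binary cross-entropy, applied to
## the fused map and every side map (deep supervision, unit weights).

checkLossInputs <- function(predicted, labels) {
  if (length(predicted) != length(labels) ||
      !identical(dim(predicted), dim(labels)))
    stop("shape mismatch between predictions and labels")
  if (!all(labels %in% c(0, 1))) stop("labels must be strictly binary")
  if (min(predicted) < 0 || max(predicted) > 1)
    stop("predicted probabilities must lie in [0, 1]")
  invisible(TRUE)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(y * p) + eps) / (sum(y) + sum(p) + eps)`, where `y` are
#' binary pixel labels and `p` predicted probabilities. The Dice coefficient
#' measures overlap between the two masks; the smoothing term `eps` avoids
#' 0/0 on empty masks.
#'
#' @param predicted numeric vector/array of probabilities in `[0, 1]`.
#' @param labels binary labels, same shape.
#' @param eps smoothing constant (default 1e-6).
#' @return loss in `[0, 1]` (0 at perfect overlap, 1 at none).
#' @examples
#' diceLoss(c(1, 0, 0, 0), c(1, 1, 0, 0)) # Dice 2/3, loss 1/3
#' @export
diceLoss <- function(predicted, labels, eps = 1e-6) {
  checkLossInputs(predicted, labels)
  1 - (2 * sum(labels * predicted) + eps) /
    (sum(labels) + sum(predicted) + eps)
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-(y * log(p) + (1 - y) * log(1 - p))`, with
#' probabilities clipped to `[delta, 1 - delta]` for numerical stability.
#' Both classes are scored, so every pixel contributes equally whether
#' vessel or background.
#'
#' @inheritParams diceLoss
#' @param delta clipping constant (default 1e-7).
#' @return mean cross-entropy (nats).
#' @examples
#' crossEntropyLoss(c(0.5, 0.5), c(1, 0)) # log(2)
#' @export
crossEntropyLoss <- function(predicted, labels, delta = 1e-7) {
  checkLossInputs(predicted, labels)
  p <- pmin(pmax(predicted, delta), 1 - delta)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Deep-supervised combined loss
#'
#' Sums `diceLoss + crossEntropyLoss` over the fused probability map and
#' all six side maps with unit weights.
#'
#' @param output a [NetworkOutput-class] object (or a plain list with
#'   elements `fused` and `side` holding probability arrays).
#' @param labels binary label array matching the maps' spatial size.
#' @return total loss, with a named per-map breakdown in attribute
#'   `"breakdown"`.
#' @export
combinedLoss <- function(output, labels) {
  side <- if (is(output, "NetworkOutput")) output@side else output$side
  fused <- if (is(output, "NetworkOutput")) output@fused else output$fused
  maps <- c(list(fused = fused),
            if (length(side))
              stats::setNames(side, paste0("side", seq_along(side))))
  labels <- as.numeric(labels)
  terms <- vapply(maps, function(m)
    diceLoss(as.numeric(m), labels) + crossEntropyLoss(as.numeric(m), labels),
    numeric(1))
  structure(sum(terms), breakdown = terms)
}

## Tensor-level combined loss over the 7 logit tensors (training path).
combinedLossT <- function(logits, y) {
  terms <- lapply(c(list(logits$fused), logits$side), function(lg) {
    p <- agSigmoid(lg)
    agSumScalars(list(agDiceLoss(p, y), agBCELoss(p, y)))
  })
  agSumScalars(terms)
}
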