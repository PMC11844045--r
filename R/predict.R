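## Prediction and evaluation.

#' Predict vessel maps for a set of images
#'
#' Runs the network in evaluation mode on each sample (zero-padding to a
#' multiple of 32 and cropping back), producing the fused probability map
#' and its thresholded binary mask. When `outDir` is given, probabilities
#' are written as 16-bit PNG under `prob/` and binary masks as 8-bit PNG
#' under `pred/`.
#'
#' @param net a [VesselNet-class] or a checkpoint path for
#'   [loadCheckpoint()].
#' @param data list of [FundusSample-class] objects or a dataset directory.
#' @param threshold binarization threshold (default 0.5).
#' @param outDir optional output directory.
#' @return named list (by sample id) of lists with `prob` and `mask`
#'   matrices at the original image size.
#' @export
predictNetwork <- function(net, data, threshold = 0.5, outDir = NULL) {
  if (is.character(net)) net <- loadCheckpoint(net)
  samples <- if (is.character(data)) readFundusDataset(data) else data
  if (!is.null(outDir)) {
    dir.create(file.path(outDir, "prob"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(outDir, "pred"), recursive = TRUE,
               showWarnings = FALSE)
  }
  out <- lapply(samples, function(s) {
    img <- as.matrix(if (length(dim(s@image)) == 3L)
      extractGreenNormalize(s)@image else s@image)
    d <- dim(img)
    p <- padTo32(img)
    res <- networkForward(net, array(p$x, c(dim(p$x), 1L, 1L)))
    prob <- res@fused[seq_len(d[1]), seq_len(d[2]), 1L, 1L]
    mask <- (prob > threshold) * 1
    if (!is.null(outDir)) {
      writeImage(prob, file.path(outDir, "prob", paste0(s@id, ".png")),
                 type = "png", bits.per.sample = 16L)
      writeImage(mask, file.path(outDir, "pred", paste0(s@id, ".png")),
                 type = "png", bits.per.sample = 8L)
    }
    list(prob = prob, mask = mask)
  })
  names(out) <- vapply(samples, sampleId, character(1))
  out
}

readMaskDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$"))
  out <- lapply(files, function(f) {
    m <- readOneImage(file.path(dir, f))
    matrix(as.numeric(m > 0.5), nrow(m), ncol(m))
  })
  names(out) <- sub("\\.png$", "", files)
  out
}

#' Evaluate predicted masks against ground truth
#'
#' Pools pixel confusion counts over all matched ids (per-image metrics
#' are also returned), optionally restricted to field-of-view masks.
#'
#' @param predictions named list of binary matrices, or a directory of PNG
#'   masks (as written by [predictNetwork()] under `pred/`).
#' @param truth named list of binary matrices, or a directory of PNG masks.
#' @param fov optional named list / directory of binary FOV masks.
#' @param csv optional path; the per-image + pooled table is written there.
#' @return list with `metrics` (pooled, named numeric), `counts`, and
#'   `perImage` (data frame).
#' @export
evaluateSegmentation <- function(predictions, truth, fov = NULL,
                                 csv = NULL) {
  if (is.character(predictions)) predictions <- readMaskDir(predictions)
  if (is.character(truth)) truth <- readMaskDir(truth)
  if (is.character(fov)) fov <- readMaskDir(fov)
  missing <- setdiff(names(truth), names(predictions))
  extra <- setdiff(names(predictions), names(truth))
  if (length(missing) || length(extra))
    stop("id mismatch between predictions and truth: ",
         paste(c(missing, extra), collapse = ", "))
  ids <- names(truth)
  total <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[[i]]
    cc <- confusionCounts(predictions[[id]], truth[[id]],
                          if (is.null(fov)) NULL else fov[[id]])
    total <- total + cc
    rows[[i]] <- data.frame(id = id, t(computeMetrics(cc)))
  }
  pooled <- computeMetrics(total)
  perImage <- do.call(rbind, rows)
  tab <- rbind(perImage, data.frame(id = "pooled", t(pooled)))
  if (!is.null(csv)) write.csv(tab, csv, row.names = FALSE)
  list(metrics = pooled, counts = total, perImage = perImage)
}
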