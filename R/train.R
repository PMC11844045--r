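## Training loop: Adam on the deep-supervised Dice + cross-entropy
## objective. Images are zero-padded to multiples of 32 for the nested
## pooling ladder and cropped back at prediction time.

padTo32 <- function(m) {
  d <- dim(m)
  H <- max(64L, as.integer(ceiling(d[1] / 32) * 32))
  W <- max(64L, as.integer(ceiling(d[2] / 32) * 32))
  if (H == d[1] && W == d[2]) return(list(x = m, pad = c(0L, 0L)))
  out <- matrix(0, H, W)
  out[seq_len(d[1]), seq_len(d[2])] <- m
  list(x = out, pad = c(H - d[1], W - d[2]))
}

newAdam <- function(params, lr, wd, beta1 = 0.9, beta2 = 0.999,
                    eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$wd <- wd; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$t <- 0L
  e$m <- lapply(params, function(p) zerosLike(p$v))
  e$s <- lapply(params, function(p) zerosLike(p$v))
  e
}

adamStep <- function(opt, params) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad + opt$wd * p$v
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$s[[i]] <- opt$beta2 * opt$s[[i]] + (1 - opt$beta2) * g * g
    p$v <- p$v - opt$lr * (opt$m[[i]] / bc1) /
      (sqrt(opt$s[[i]] / bc2) + opt$eps)
    p$grad <- NULL
  }
}

## Dice coefficient between two binary masks (the overlap statistic used
## for validation monitoring and the smoke test).
#' Dice coefficient of two binary masks
#'
#' `2|X & Y| / (|X| + |Y|)`; returns 1 when both masks are empty.
#'
#' @param a,b binary arrays of equal shape.
#' @return Dice overlap in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

sampleTensor <- function(samples) {
  imgs <- lapply(samples, function(s) padTo32(as.matrix(s@image))$x)
  msks <- lapply(samples, function(s) padTo32(s@mask)$x)
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  x <- array(0, c(H, W, 1L, length(samples)))
  y <- array(0, c(H, W, 1L, length(samples)))
  for (i in seq_along(imgs)) {
    x[, , 1L, i] <- imgs[[i]]
    y[, , 1L, i] <- msks[[i]]
  }
  list(x = x, y = y)
}

#' Train the segmentation network
#'
#' Minimizes the deep-supervised Dice + cross-entropy loss with Adam
#' (paper recipe: batch 2, lr 0.001, weight decay 1e-4). A source-grouped
#' validation subset (`valFraction`) is carved from the training data for
#' checkpoint selection; the best-validation-Dice state is restored at the
#' end. The loss trajectory is reproducible from the seed under
#' single-threaded execution.
#'
#' @param data list of [FundusSample-class] objects (with masks) or a
#'   dataset directory for [readFundusDataset()].
#' @param config a [TrainConfig-class] (see [trainConfig()]).
#' @param netConfig a [NetworkConfig-class].
#' @param checkpoint optional path; the best state is saved there.
#' @param verbose print per-epoch loss and validation Dice.
#' @return list with `net` (the trained [VesselNet-class]), `history`
#'   (per-epoch data frame), and `iterLoss` (loss at every gradient step).
#' @export
trainNetwork <- function(data, config = trainConfig(),
                         netConfig = networkConfig(), checkpoint = NULL,
                         verbose = FALSE) {
  samples <- if (is.character(data)) readFundusDataset(data) else data
  if (!length(samples)) stop("empty dataset")
  if (any(vapply(samples, function(s) is.null(s@mask), logical(1))))
    stop("all training samples need masks")
  val <- list()
  trainSet <- samples
  nSrc <- length(unique(sourceId(vapply(samples, sampleId, character(1)))))
  if (config@valFraction > 0 && nSrc >= 5L) {
    sp <- splitDataset(samples, ratio = 1 - config@valFraction,
                       seed = config@seed)
    trainSet <- sp$train
    val <- sp$test
  }
  net <- buildNetwork(netConfig, seed = config@seed)
  tree <- net@modules$tree
  params <- collectParams(tree)
  opt <- newAdam(params, config@lr, config@weightDecay)
  iterLoss <- numeric(0)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        valDice = numeric(0))
  best <- list(score = -Inf, state = NULL)
  valDice <- function() {
    if (!length(val)) return(NA_real_)
    mean(vapply(val, function(s) {
      p <- padTo32(as.matrix(s@image))
      out <- networkForward(net, array(p$x, c(dim(p$x), 1L, 1L)))
      d <- dim(s@mask)
      pred <- (out@fused[seq_len(d[1]), seq_len(d[2]), 1L, 1L] >
                 config@threshold) * 1
      diceCoefficient(pred, s@mask)
    }, numeric(1)))
  }
  it <- 0L
  done <- FALSE
  withSeed(config@seed + 1L, {
    for (epoch in seq_len(config@epochs)) {
      ord <- sample(length(trainSet))
      epochLoss <- numeric(0)
      for (b in split(ord, ceiling(seq_along(ord) / config@batchSize))) {
        bt <- sampleTensor(trainSet[b])
        logits <- netForwardT(tree, agTensor(bt$x), training = TRUE)
        loss <- combinedLossT(logits, bt$y)
        agBackward(loss)
        adamStep(opt, params)
        it <- it + 1L
        iterLoss <- c(iterLoss, loss$v)
        epochLoss <- c(epochLoss, loss$v)
        if (!is.na(config@maxIterations) && it >= config@maxIterations) {
          done <- TRUE
          break
        }
      }
      vd <- valDice()
      score <- if (is.na(vd)) -mean(epochLoss) else vd
      if (score > best$score)
        best <- list(score = score, state = moduleState(tree))
      history[nrow(history) + 1L, ] <- list(epoch, mean(epochLoss), vd)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val Dice %s", epoch,
                        mean(epochLoss),
                        if (is.na(vd)) "-" else sprintf("%.4f", vd)))
      if (done) break
    }
  })
  if (!is.null(best$state)) loadModuleState(tree, best$state)
  if (!is.null(checkpoint)) saveCheckpoint(net, checkpoint)
  list(net = net, history = history, iterLoss = iterLoss)
}
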