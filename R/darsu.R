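## Double-Attention Residual U-blocks.
##
## DARSU-L (L in 4..7) is a small encoder-decoder: a stage-input projection
## f0, L-1 encoder conv units with 2x2 max pooling between them (L-2
## poolings), and L-2 decoder levels. At each decoder level the skip feature
## is gated by an attention gate against the deeper feature, concatenated
## with the bilinearly upsampled deeper feature, and passed through a conv
## unit. The topmost decoder output goes through spatial attention (SAM) and
## is added to f0 (the residual connection).
##
## DARSU-4F replaces all resampling with dilated convolutions (rates 2, 4, 8
## in the encoder, mirrored 4, 2, 1 in the decoder), gates each skip at
## equal resolution, and applies channel attention (CAM) instead of SAM.

#' Construct a double-attention residual U-block
#'
#' @param depth U-depth L (4-7 for the resampling variant; fixed depth-4
#'   topology when `dilated = TRUE`).
#' @param inChannels,midChannels,outChannels channel plan: the stage-input
#'   projection maps to `outChannels`, encoder/decoder levels run at
#'   `midChannels`, and the top decoder level maps back to `outChannels`.
#' @param dilated if `TRUE`, build the dilated bottleneck variant
#'   (DARSU-4F): no internal resampling, encoder dilations
#'   `c(1, dilationRates)`, CAM on the output.
#' @param dilationRates ordered dilation rates for the dilated variant
#'   (default `c(2, 4, 8)`).
#' @param attention named logical list toggling the three attention
#'   mechanisms (`gate`, `sam`, `cam`) for ablation; disabled mechanisms are
#'   identity pass-throughs, reducing the block to a plain residual U-block.
#' @param samKernel SAM convolution kernel size (odd, default 7).
#' @param camReduction CAM bottleneck reduction ratio (default 16).
#' @param seed optional integer seed for weight initialization.
#' @return a `darsuBlock` module usable with [darsuForward()].
#' @examples
#' blk <- darsuBlock(4, 1, 2, 2, seed = 1)
#' out <- darsuForward(blk, array(rnorm(64), c(8, 8, 1, 1)))
#' dim(out)
#' @export
darsuBlock <- function(depth, inChannels, midChannels, outChannels,
                       dilated = FALSE, dilationRates = c(2L, 4L, 8L),
                       attention = list(gate = TRUE, sam = TRUE, cam = TRUE),
                       samKernel = 7L, camReduction = 16L, seed = NULL) {
  withSeed(seed, {
    if (dilated) {
      depth <- 4L
      rates <- as.integer(dilationRates)
      enc <- list(newConvUnit(outChannels, midChannels, 1L))
      for (r in rates) enc <- c(enc, list(newConvUnit(midChannels, midChannels, r)))
      ndec <- length(rates)
      dec <- vector("list", ndec)
      gates <- vector("list", ndec)
      for (k in seq_len(ndec)) { # k = 1 is the top level (dilation 1)
        oc <- if (k == 1L) outChannels else midChannels
        dil <- if (k == 1L) 1L else rates[k - 1L]
        dec[[k]] <- newConvUnit(2L * midChannels, oc, dil)
        gates[[k]] <- newAttnGate(midChannels, midChannels)
      }
      structure(list(depth = depth, dilated = TRUE, rates = rates,
                     inChannels = as.integer(inChannels),
                     outChannels = as.integer(outChannels),
                     attention = attention,
                     f0 = newConvUnit(inChannels, outChannels),
                     enc = enc, dec = dec, gates = gates,
                     cam = newCAM(outChannels, camReduction)),
                class = c("darsuBlock", "dnModule"))
    } else {
      if (!depth %in% 4:7) stop("depth must be in 4..7")
      L <- as.integer(depth)
      enc <- list(newConvUnit(outChannels, midChannels))
      for (k in 2:(L - 1L)) enc <- c(enc, list(newConvUnit(midChannels, midChannels)))
      dec <- vector("list", L - 2L)
      gates <- vector("list", L - 2L)
      for (k in seq_len(L - 2L)) { # k = 1 is the top level
        oc <- if (k == 1L) outChannels else midChannels
        dec[[k]] <- newConvUnit(2L * midChannels, oc)
        gates[[k]] <- newAttnGate(midChannels, midChannels)
      }
      structure(list(depth = L, dilated = FALSE,
                     inChannels = as.integer(inChannels),
                     outChannels = as.integer(outChannels),
                     attention = attention,
                     f0 = newConvUnit(inChannels, outChannels),
                     enc = enc, dec = dec, gates = gates,
                     sam = newSAM(samKernel)),
                class = c("darsuBlock", "dnModule"))
    }
  })
}

## Tensor-level forward. `trace`, when an environment, collects the spatial
## size of every internal feature map (instrumentation for tests).
fwdDarsu <- function(blk, x, training = FALSE, trace = NULL) {
  note <- function(t) {
    if (!is.null(trace)) trace$sizes <- c(trace$sizes, list(dim(t$v)[1:2]))
    t
  }
  att <- blk$attention
  f0 <- note(fwdConvUnit(blk$f0, x, training))
  if (blk$dilated) {
    h <- f0
    skips <- list()
    for (k in seq_along(blk$enc)) {
      h <- note(fwdConvUnit(blk$enc[[k]], h, training))
      if (k < length(blk$enc)) skips[[k]] <- h
    }
    d <- h
    for (k in seq(length(blk$dec), 1L)) {
      xs <- skips[[k]]
      xa <- if (isTRUE(att$gate)) fwdAttnGate(blk$gates[[k]], xs, d) else xs
      d <- note(fwdConvUnit(blk$dec[[k]], agConcatC(list(xa, d)), training))
    }
    out <- if (isTRUE(att$cam)) fwdCAM(blk$cam, d) else d
  } else {
    L <- blk$depth
    dx <- dim(x$v)
    if (dx[1] %% 2L^(L - 2L) || dx[2] %% 2L^(L - 2L))
      stop("input must be divisible by 2^(L-2)")
    h <- f0
    skips <- vector("list", L - 2L)
    for (k in seq_len(L - 1L)) {
      h <- note(fwdConvUnit(blk$enc[[k]], h, training))
      if (k <= L - 2L) {
        skips[[k]] <- h
        h <- agMaxPool2(h)
      }
    }
    d <- h
    for (k in seq(L - 2L, 1L)) {
      xs <- skips[[k]]
      xa <- if (isTRUE(att$gate)) fwdAttnGate(blk$gates[[k]], xs, d) else xs
      up <- agUpsample(d, dim(xs$v)[1], dim(xs$v)[2])
      d <- note(fwdConvUnit(blk$dec[[k]], agConcatC(list(xa, up)), training))
    }
    out <- if (isTRUE(att$sam)) fwdSAM(blk$sam, d) else d
  }
  agAdd(out, f0)
}

#' Run a DARSU block on a feature map
#'
#' @param block module from [darsuBlock()].
#' @param x feature map `[H, W, C, N]` with `C = inChannels`; for the
#'   resampling variant the spatial size must be divisible by `2^(L-2)`.
#' @param training logical; batch versus running statistics in BN.
#' @return feature map `[H, W, outChannels, N]`.
#' @export
darsuForward <- function(block, x, training = FALSE) {
  x <- asFeatureMap(x)
  if (dim(x)[3] != block$inChannels)
    stop("channel mismatch: input has ", dim(x)[3], ", block expects ",
         block$inChannels)
  if (training) fwdDarsu(block, agTensor(x), training = TRUE)$v
  else agNoGrad(fwdDarsu(block, agTensor(x), training = FALSE)$v)
}

#' Count attention gates in a module
#'
#' Walks a block or network and counts attention-gate sub-modules; a
#' DARSU-L block contains exactly L - 2 (one per gated skip), the dilated
#' variant one per decoder level.
#'
#' @param module a `darsuBlock` or `VesselNet` module tree.
#' @return integer count.
#' @export
countAttentionGates <- function(module) {
  if (is(module, "VesselNet")) module <- module@modules$tree
  countModules(module, "dnAttnGate")
}

#' Spatial sizes of every internal feature map of a block
#'
#' Instrumentation used to verify that the dilated variant preserves the
#' spatial size at every layer.
#'
#' @param block module from [darsuBlock()].
#' @param x input feature map.
#' @return list of `c(H, W)` pairs, one per internal conv-unit output.
#' @export
darsuLayerSizes <- function(block, x) {
  tr <- new.env(parent = emptyenv())
  tr$sizes <- list()
  agNoGrad(fwdDarsu(block, agTensor(asFeatureMap(x)), training = FALSE,
                    trace = tr))
  tr$sizes
}

#' Gradient-support receptive field of the dilated encoder chain
#'
#' Builds a copy of the dilated block's encoder chain with all-positive
#' kernels (so ReLU never clips inside the support), runs it on a constant
#' input, backpropagates from the centre output pixel, and measures the
#' width of the nonzero gradient support along one axis. For 3x3 kernels
#' with dilations (1, 2, 4, 8) the field spans 1 + 2*(1+2+4+8) = 31 pixels.
#'
#' @param block a dilated block from `darsuBlock(dilated = TRUE)`.
#' @param inputSize spatial size of the probe input (default 64).
#' @return integer support width in pixels.
#' @export
dilatedReceptiveField <- function(block, inputSize = 64L) {
  if (!isTRUE(block$dilated)) stop("block is not the dilated variant")
  old <- .ag$grad_on
  .ag$grad_on <- TRUE
  on.exit(.ag$grad_on <- old)
  ic <- dim(block$enc[[1]]$conv$w$v)[3]
  x <- agTensor(array(1, c(inputSize, inputSize, ic, 1L)), requires = TRUE)
  h <- x
  for (k in seq_along(block$enc)) {
    u <- block$enc[[k]]
    pos <- newConvUnit(dim(u$conv$w$v)[3], dim(u$conv$w$v)[4], u$conv$dil)
    pos$conv$w$v <- abs(u$conv$w$v) + 0.01
    pos$conv$b$v <- rep(0.1, length(u$conv$b$v))
    h <- fwdConvUnit(pos, h, training = FALSE)
  }
  ctr <- (inputSize %/% 2L)
  mask <- array(0, dim(h$v))
  mask[ctr, ctr, , 1L] <- 1
  agBackward(agSumAll(agMulB(h, agTensor(mask))))
  support <- which(apply(abs(x$grad) > 0, 1, any))
  diff(range(support)) + 1L
}
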