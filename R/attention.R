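#' @useDynLib darsunet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

## Functional surface over the attention primitives: plain-array in,
## plain-array out, with explicit weight lists, so each operator can be
## checked against straight-line scalar arithmetic.

#' Validate and coerce a feature map
#'
#' Feature maps are 4-D numeric arrays laid out `[H, W, C, N]` (rows,
#' columns, channels, batch). A matrix is promoted to `[H, W, 1, 1]`, a 3-D
#' array to a single-sample batch.
#'
#' @param x numeric array (2-D, 3-D, or 4-D) with finite values.
#' @return a 4-D array `[H, W, C, N]`.
#' @examples
#' dim(asFeatureMap(matrix(0, 8, 8)))
#' @export
asFeatureMap <- function(x) {
  if (is.null(dim(x))) stop("feature map must be an array")
  d <- dim(x)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("feature map must have 2-4 dimensions")
  if (any(dim(x) < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(x))) stop("feature map values must be finite")
  x
}

agWrap <- function(arr) agTensor(asFeatureMap(arr))

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

gateFromWeights <- function(w) {
  m <- newAttnGate(dim(w$wx)[3], dim(w$wg)[3], dim(w$wx)[4])
  m$wx$w$v <- w$wx; m$wx$b$v <- w$bx
  m$wg$w$v <- w$wg; m$wg$b$v <- w$bg
  m$psi$w$v <- w$psi; m$psi$b$v <- w$bpsi
  m
}

#' Initialize attention-gate weights
#'
#' The gate projects the skip feature `x` (`channelsX` channels) and the
#' gating feature `g` (`channelsG` channels) to `fint` intermediate channels
#' with 1x1 convolutions; a third 1x1 convolution (`psi`) maps the ReLU of
#' their sum to a single-channel coefficient logit. `fint` defaults to half
#' of the skip's channels (at least 1).
#'
#' @param channelsX,channelsG channel counts of the skip and gating features.
#' @param fint intermediate channel count (default `max(1, channelsX %/% 2)`).
#' @param seed optional integer for reproducible initialization.
#' @return a list of arrays `wx, bx, wg, bg, psi, bpsi` (1x1 kernels and
#'   biases).
#' @seealso [attentionGate()]
#' @export
initAttentionGate <- function(channelsX, channelsG, fint = NULL, seed = NULL) {
  withSeed(seed, {
    if (is.null(fint)) fint <- max(1L, channelsX %/% 2L)
    list(wx = initKernel(1L, 1L, channelsX, fint), bx = numeric(fint),
         wg = initKernel(1L, 1L, channelsG, fint), bg = numeric(fint),
         psi = initKernel(1L, 1L, fint, 1L), bpsi = numeric(1L))
  })
}

#' Attention gate on a skip connection
#'
#' Computes `alpha = sigmoid(psi(ReLU(wx*x + up(wg*g))))` and returns
#' `alpha * x`, where `up` bilinearly upsamples the projected gating signal
#' to the skip's resolution when `g` is at half resolution. The coefficient
#' map `alpha` is single-channel, strictly inside (0, 1), and broadcast over
#' the skip's channels.
#'
#' @param x skip feature map `[H, W, C, N]`.
#' @param g gating feature map at the same or half spatial resolution,
#'   same batch size.
#' @param weights weight list from [initAttentionGate()].
#' @return gated feature map with `x`'s shape; the coefficient map is
#'   attached as attribute `"alpha"`.
#' @examples
#' w <- initAttentionGate(2, 2, seed = 1)
#' out <- attentionGate(array(1, c(8, 8, 2, 1)), array(1, c(4, 4, 2, 1)), w)
#' dim(out)
#' @export
attentionGate <- function(x, g, weights) {
  agNoGrad({
    r <- fwdAttnGate(gateFromWeights(weights), agWrap(x), agWrap(g),
                     return_alpha = TRUE)
    structure(r$out$v, alpha = r$alpha$v)
  })
}

#' Initialize spatial-attention (SAM) weights
#'
#' @param kernelSize odd convolution kernel size (default 7).
#' @param seed optional integer seed.
#' @return list with the `[k, k, 2, 1]` kernel `w` and bias `b`.
#' @export
initSpatialAttention <- function(kernelSize = 7L, seed = NULL) {
  if (kernelSize %% 2L == 0L) stop("kernel must be odd")
  withSeed(seed, list(w = initKernel(kernelSize, kernelSize, 2L, 1L),
                      b = numeric(1L)))
}

#' Spatial attention (SAM)
#'
#' Channel-wise mean and max pooling give two `H x W` maps; stacked, they
#' pass through one `k x k` convolution and a sigmoid to a per-pixel
#' coefficient map that scales every channel of the input.
#'
#' @param x feature map `[H, W, C, N]`.
#' @param weights list from [initSpatialAttention()].
#' @return feature map of `x`'s shape with attribute `"alpha"`.
#' @export
spatialAttention <- function(x, weights) {
  k <- dim(weights$w)[1]
  if (k %% 2L == 0L) stop("kernel must be odd")
  agNoGrad({
    m <- newSAM(k)
    m$conv$w$v <- weights$w
    m$conv$b$v <- weights$b
    r <- fwdSAM(m, agWrap(x), return_alpha = TRUE)
    structure(r$out$v, alpha = r$alpha$v)
  })
}

#' Initialize channel-attention (CAM) weights
#'
#' @param channels input channel count C.
#' @param reduction bottleneck reduction ratio r; the shared transform maps
#'   C to `max(1, C %/% r)` and back (default 16).
#' @param seed optional integer seed.
#' @return list of 1x1 kernels and biases `w1, b1, w2, b2`.
#' @export
initChannelAttention <- function(channels, reduction = 16L, seed = NULL) {
  if (reduction < 1L) stop("reduction must be >= 1")
  cr <- max(1L, channels %/% as.integer(reduction))
  withSeed(seed, list(w1 = initKernel(1L, 1L, channels, cr), b1 = numeric(cr),
                      w2 = initKernel(1L, 1L, cr, channels),
                      b2 = numeric(channels)))
}

#' Channel attention (CAM)
#'
#' Global spatial mean and max pooling produce two C-vectors; each passes
#' through the same two-layer bottleneck transform (C -> C/r, ReLU, C/r ->
#' C); the branch outputs are summed and a sigmoid yields per-channel
#' weights that scale every pixel of the corresponding channel.
#'
#' @param x feature map `[H, W, C, N]`.
#' @param weights list from [initChannelAttention()].
#' @return feature map of `x`'s shape with attribute `"alpha"` (the
#'   `[1, 1, C, N]` channel weights).
#' @export
channelAttention <- function(x, weights) {
  agNoGrad({
    c <- dim(weights$w1)[3]
    cr <- dim(weights$w1)[4]
    m <- structure(list(fc1 = newConv(1L, c, cr), fc2 = newConv(1L, cr, c)),
                   class = c("dnCAM", "dnModule"))
    m$fc1$w$v <- weights$w1; m$fc1$b$v <- weights$b1
    m$fc2$w$v <- weights$w2; m$fc2$b$v <- weights$b2
    r <- fwdCAM(m, agWrap(x), return_alpha = TRUE)
    structure(r$out$v, alpha = r$alpha$v)
  })
}

#' Convolution + batch normalization + ReLU unit
#'
#' The basic unit of every residual U-block: a 3x3 same-padding convolution
#' (padding equals the dilation rate, so spatial size is preserved), batch
#' normalization, and a ReLU.
#'
#' @param x feature map `[H, W, C, N]` with C equal to the kernel's input
#'   channels.
#' @param weights list with `w` (`[3, 3, IC, OC]`), `b`, `gamma`, `beta`,
#'   `runMean`, `runVar`; see [initConvUnit()].
#' @param dilation dilation rate (>= 1).
#' @param training logical; `TRUE` normalizes with batch statistics,
#'   `FALSE` with the stored running moments.
#' @return feature map `[H, W, OC, N]`, elementwise non-negative.
#' @export
convBNReLU <- function(x, weights, dilation = 1L, training = FALSE) {
  x <- asFeatureMap(x)
  if (dim(x)[3] != dim(weights$w)[3])
    stop("channel mismatch: input has ", dim(x)[3], ", kernel expects ",
         dim(weights$w)[3])
  agNoGrad({
    m <- newConvUnit(dim(weights$w)[3], dim(weights$w)[4], dilation)
    m$conv$w$v <- weights$w; m$conv$b$v <- weights$b
    m$bn$gamma$v <- weights$gamma; m$bn$beta$v <- weights$beta
    m$bn$state$rm <- weights$runMean; m$bn$state$rv <- weights$runVar
    fwdConvUnit(m, agTensor(x), training = training)$v
  })
}

#' Initialize a conv + BN + ReLU unit
#'
#' @param inChannels,outChannels channel counts.
#' @param seed optional integer seed.
#' @return weight list for [convBNReLU()]; BN is initialized to the
#'   identity transform (unit scale, zero shift, zero running mean, unit
#'   running variance).
#' @export
initConvUnit <- function(inChannels, outChannels, seed = NULL) {
  withSeed(seed, list(w = initKernel(3L, 3L, inChannels, outChannels),
                      b = numeric(outChannels),
                      gamma = rep(1, outChannels), beta = numeric(outChannels),
                      runMean = numeric(outChannels),
                      runVar = rep(1, outChannels)))
}
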