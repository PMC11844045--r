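## Network assembly: a two-level nested U. The outer U has six encoder
## stages (joined by 2x2 max pooling) and five decoder stages (joined by
## bilinear upsampling and concatenation with the mirror encoder output);
## every stage is itself a residual U-block. Stage plan:
##   En1/De1 -> DARSU-7, En2/De2 -> DARSU-6, En3/De3 -> DARSU-5,
##   En4/De4 -> DARSU-4, En5/En6/De5 -> DARSU-4F (dilated bottleneck).
## Each decoder stage and the deepest encoder emit a single-channel side
## logit (3x3 conv, upsampled to input size); the six side logits are fused
## by a 1x1 convolution into the final logit. Sigmoid turns all seven into
## probability maps (deep supervision applies the loss to each).

stagePlan <- function(bw) {
  enOut <- bw * c(1L, 2L, 4L, 8L, 8L, 8L)
  deOut <- bw * c(1L, 1L, 2L, 4L, 8L) # De1..De5
  list(enDepth = c(7L, 6L, 5L, 4L, NA, NA), # NA = dilated variant
       enOut = enOut,
       deDepth = c(7L, 6L, 5L, 4L, NA),
       deOut = deOut,
       ## decoder inputs: concat(upsampled deeper output, mirror encoder)
       deIn = c(enOut[1] + deOut[2], enOut[2] + deOut[3],
                enOut[3] + deOut[4], enOut[4] + deOut[5],
                enOut[5] + enOut[6]))
}

midOf <- function(oc) max(2L, oc %/% 2L)

#' Build the double-attention nested U-network
#'
#' @param config a [NetworkConfig-class] (see [networkConfig()]).
#' @param seed integer seed; two builds with the same seed have identical
#'   parameters.
#' @return a [VesselNet-class] object.
#' @examples
#' net <- buildNetwork(networkConfig(baseWidth = 4), seed = 1)
#' parameterCount(net)
#' @export
buildNetwork <- function(config, seed = 0L) {
  stopifnot(is(config, "NetworkConfig"))
  validObject(config)
  bw <- config@baseWidth
  sp <- stagePlan(bw)
  att <- config@attention
  withSeed(seed, {
    mk <- function(depth, ic, oc) {
      if (is.na(depth))
        darsuBlock(4L, ic, midOf(oc), oc, dilated = TRUE, attention = att,
                   samKernel = config@samKernel,
                   camReduction = config@camReduction)
      else
        darsuBlock(depth, ic, midOf(oc), oc, attention = att,
                   samKernel = config@samKernel,
                   camReduction = config@camReduction)
    }
    en <- vector("list", 6L)
    icur <- config@inChannels
    for (k in 1:6) {
      en[[k]] <- mk(sp$enDepth[k], icur, sp$enOut[k])
      icur <- sp$enOut[k]
    }
    de <- vector("list", 5L)
    for (k in 1:5) de[[k]] <- mk(sp$deDepth[k], sp$deIn[k], sp$deOut[k])
    ## side heads: De1..De5 then En6
    sideC <- c(sp$deOut, sp$enOut[6])
    side <- lapply(sideC, function(c) newConv(3L, c, 1L))
    fuse <- newConv(1L, 6L, 1L)
    tree <- list(en = en, de = de, side = side, fuse = fuse)
    env <- new.env(parent = emptyenv())
    env$tree <- tree
    new("VesselNet", config = config, modules = env, seed = as.integer(seed))
  })
}

#' Number of trainable parameters
#'
#' @param net a [VesselNet-class] object.
#' @return integer parameter count.
#' @export
parameterCount <- function(net) {
  sum(vapply(collectParams(net@modules$tree), function(p) length(p$v),
             numeric(1)))
}

checkInputSize <- function(d) {
  if (d[1] < 64L || d[2] < 64L || d[1] %% 32L || d[2] %% 32L)
    stop("pad or resize to multiple of 32")
}

## Tensor-level forward pass; returns the 7 logit tensors.
netForwardT <- function(tree, x, training = FALSE) {
  d <- dim(x$v)
  s <- vector("list", 6L)
  h <- x
  for (k in 1:6) {
    s[[k]] <- fwdDarsu(tree$en[[k]], h, training)
    if (k < 6L) h <- agMaxPool2(s[[k]])
  }
  dcur <- s[[6L]]
  dout <- vector("list", 5L)
  for (k in 5:1) {
    mirror <- s[[k]]
    up <- agUpsample(dcur, dim(mirror$v)[1], dim(mirror$v)[2])
    dcur <- fwdDarsu(tree$de[[k]], agConcatC(list(up, mirror)), training)
    dout[[k]] <- dcur
  }
  heads <- c(dout, list(s[[6L]]))
  sideLogits <- vector("list", 6L)
  for (k in 1:6)
    sideLogits[[k]] <- agUpsample(fwdConv(tree$side[[k]], heads[[k]]),
                                  d[1], d[2])
  fusedLogit <- fwdConv(tree$fuse, agConcatC(sideLogits))
  list(fused = fusedLogit, side = sideLogits)
}

#' Forward pass of the segmentation network
#'
#' Runs the network in evaluation mode (running BN statistics, no gradient
#' tape) on an image batch and returns the fused probability map plus the
#' six side maps used for deep supervision.
#'
#' @param net a [VesselNet-class] object.
#' @param image feature map `[H, W, C, N]` (a matrix is promoted); H and W
#'   must be multiples of 32 and at least 64.
#' @return a [NetworkOutput-class] object.
#' @export
networkForward <- function(net, image) {
  x <- asFeatureMap(image)
  checkInputSize(dim(x))
  if (dim(x)[3] != net@config@inChannels)
    stop("channel mismatch: input has ", dim(x)[3], ", network expects ",
         net@config@inChannels)
  agNoGrad({
    out <- netForwardT(net@modules$tree, agTensor(x), training = FALSE)
    sig <- function(t) 1 / (1 + exp(-t$v))
    new("NetworkOutput",
        fused = sig(out$fused), side = lapply(out$side, sig),
        fusedLogit = out$fused$v,
        sideLogits = lapply(out$side, function(t) t$v))
  })
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a single serialized archive holding the configuration,
#' the build seed, and every parameter and BN running moment; loading
#' rebuilds the network and restores the state, so a save/load round trip
#' reproduces the forward pass bitwise.
#'
#' @param net a [VesselNet-class] object.
#' @param path file path.
#' @return `loadCheckpoint` returns the restored [VesselNet-class].
#' @export
saveCheckpoint <- function(net, path) {
  cfg <- net@config
  saveRDS(list(format = "darsunet-checkpoint-1",
               config = list(baseWidth = cfg@baseWidth,
                             inChannels = cfg@inChannels,
                             attention = cfg@attention,
                             samKernel = cfg@samKernel,
                             camReduction = cfg@camReduction),
               seed = net@seed,
               state = moduleState(net@modules$tree)),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt checkpoint: ", conditionMessage(e)))
  if (!identical(ck$format, "darsunet-checkpoint-1"))
    stop("corrupt checkpoint: unrecognized format")
  net <- buildNetwork(do.call(networkConfig, ck$config), seed = ck$seed)
  loadModuleState(net@modules$tree, ck$state)
  net
}
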