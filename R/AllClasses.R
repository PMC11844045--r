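#' @importFrom stats rnorm runif quantile
#' @importFrom utils read.csv write.csv head
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' FundusSample: one image with its ground truth
#'
#' The dataset record: a fundus image (grayscale matrix or H x W x 3 RGB
#' array, values in `[0, 1]`), a binary vessel mask, an optional binary
#' field-of-view (FOV) mask marking the imaged retinal disk, and an
#' identifier.
#'
#' @slot image numeric matrix or 3-channel array in `[0, 1]`.
#' @slot mask binary matrix (vessel ground truth) or NULL.
#' @slot fov binary matrix or NULL.
#' @slot id character identifier.
#' @aliases FundusSample
#' @exportClass FundusSample
setClass("FundusSample",
  representation(image = "array", mask = "matrixOrNULL",
                 fov = "matrixOrNULL", id = "character"),
  validity = function(object) {
    d <- dim(object@image)
    if (!length(d) %in% c(2L, 3L)) return("image must be 2-D or H x W x C")
    hw <- d[1:2]
    for (nm in c("mask", "fov")) {
      m <- slot(object, nm)
      if (!is.null(m)) {
        if (!identical(dim(m), hw)) return(paste(nm, "size differs from image"))
        if (!all(m %in% c(0, 1))) return(paste(nm, "must be binary"))
      }
    }
    if (length(object@id) != 1L) return("id must be a single string")
    TRUE
  })

#' Construct a FundusSample
#'
#' @param image numeric matrix or `H x W x 3` array, values in `[0, 1]`.
#' @param mask,fov binary matrices of the image's spatial size, or NULL.
#' @param id identifier string.
#' @return a [FundusSample-class] object.
#' @export
fundusSample <- function(image, mask = NULL, fov = NULL, id = "sample") {
  if (is.matrix(image)) image <- array(image, dim(image))
  new("FundusSample", image = image, mask = mask, fov = fov, id = id)
}

#' @describeIn fundusSample image accessor
#' @param x a `FundusSample`.
#' @export
sampleImage <- function(x) x@image

#' @describeIn fundusSample mask accessor
#' @export
sampleMask <- function(x) x@mask

#' @describeIn fundusSample FOV accessor
#' @export
sampleFOV <- function(x) x@fov

#' @describeIn fundusSample identifier accessor
#' @export
sampleId <- function(x) x@id

setMethod("show", "FundusSample", function(object) {
  d <- dim(object@image)
  cat("FundusSample '", object@id, "': ", d[1], "x", d[2],
      if (length(d) == 3L) paste0(" x", d[3], " channels") else " grayscale",
      if (!is.null(object@mask)) sprintf(", mask (%.1f%% vessel)",
                                         100 * mean(object@mask)) else "",
      if (!is.null(object@fov)) ", fov" else "", "\n", sep = "")
})

#' PhantomSpec: parameters of one synthetic fundus phantom
#'
#' A seed plus geometry and noise parameters that fully determine one
#' synthetic fundus image: curvilinear vessel trees grown by seeded random
#' walks inside a circular field of view over a smooth radial background.
#'
#' @slot seed integer RNG seed; the phantom is a pure function of the spec.
#' @slot size image side in pixels (>= 64).
#' @slot nRoots number of vessel roots on the FOV rim.
#' @slot rootWidth root vessel width in pixels.
#' @slot widthDecay width multiplier per child branch.
#' @slot branchProb branching probability per walk step.
#' @slot curvatureSigma direction jitter (radians) per step.
#' @slot vesselContrast intensity drop under vessels.
#' @slot noiseSigma Gaussian noise standard deviation.
#' @slot fovRadiusFrac FOV radius as a fraction of the image side.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(seed = "integer", size = "integer", nRoots = "integer",
                 rootWidth = "numeric", widthDecay = "numeric",
                 branchProb = "numeric", curvatureSigma = "numeric",
                 vesselContrast = "numeric", noiseSigma = "numeric",
                 fovRadiusFrac = "numeric"),
  validity = function(object) {
    if (object@size < 64L) return("size must be >= 64")
    if (object@fovRadiusFrac <= 0 || object@fovRadiusFrac > 0.5)
      return("fovRadiusFrac must be in (0, 0.5]")
    if (object@rootWidth < 1) return("rootWidth must be >= 1 px")
    TRUE
  })

#' Construct a PhantomSpec
#'
#' @param seed integer seed.
#' @param size image side in pixels.
#' @param nRoots,rootWidth,widthDecay,branchProb,curvatureSigma vessel-tree
#'   geometry parameters; see [PhantomSpec-class].
#' @param vesselContrast,noiseSigma,fovRadiusFrac appearance parameters.
#' @return a [PhantomSpec-class] object.
#' @export
phantomSpec <- function(seed = 0L, size = 128L, nRoots = 4L, rootWidth = 3,
                        widthDecay = 0.7, branchProb = 0.05,
                        curvatureSigma = 0.15, vesselContrast = 0.35,
                        noiseSigma = 0.03, fovRadiusFrac = 0.48) {
  new("PhantomSpec", seed = as.integer(seed), size = as.integer(size),
      nRoots = as.integer(nRoots), rootWidth = rootWidth,
      widthDecay = widthDecay, branchProb = branchProb,
      curvatureSigma = curvatureSigma, vesselContrast = vesselContrast,
      noiseSigma = noiseSigma, fovRadiusFrac = fovRadiusFrac)
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: seed %d, %dx%d, %d roots (width %.1f px)\n",
              object@seed, object@size, object@size, object@nRoots,
              object@rootWidth))
})

#' NetworkConfig: architecture settings
#'
#' The stage plan is fixed — six encoder stages and five decoder stages
#' using residual U-blocks of depths 7, 6, 5, 4 plus the dilated depth-4
#' bottleneck variant (4F) for the two deepest encoders and the deepest
#' decoder. Only channel widths and attention toggles vary.
#'
#' @slot baseWidth channel multiplier; encoder output widths are
#'   `baseWidth * c(1, 2, 4, 8, 8, 8)`.
#' @slot inChannels input channels (1 after preprocessing).
#' @slot attention named logical list: `gate`, `sam`, `cam`.
#' @slot samKernel SAM kernel size.
#' @slot camReduction CAM reduction ratio.
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(baseWidth = "integer", inChannels = "integer",
                 attention = "list", samKernel = "integer",
                 camReduction = "integer"),
  validity = function(object) {
    if (object@baseWidth < 2L) return("baseWidth must be >= 2")
    if (!all(c("gate", "sam", "cam") %in% names(object@attention)))
      return("attention must name gate, sam, cam")
    TRUE
  })

#' Construct a NetworkConfig
#'
#' @param baseWidth channel multiplier (default 16; use 4 for quick
#'   experiments, 32-64 for full scale).
#' @param inChannels input channel count (default 1).
#' @param attention named logical list toggling `gate`, `sam`, `cam`.
#' @param samKernel,camReduction attention hyperparameters.
#' @return a [NetworkConfig-class] object.
#' @export
networkConfig <- function(baseWidth = 16L, inChannels = 1L,
                          attention = list(gate = TRUE, sam = TRUE,
                                           cam = TRUE),
                          samKernel = 7L, camReduction = 16L) {
  new("NetworkConfig", baseWidth = as.integer(baseWidth),
      inChannels = as.integer(inChannels), attention = attention,
      samKernel = as.integer(samKernel),
      camReduction = as.integer(camReduction))
}

setMethod("show", "NetworkConfig", function(object) {
  att <- paste(names(Filter(isTRUE, object@attention)), collapse = "+")
  cat(sprintf(
    "NetworkConfig: base width %d, %d input channel(s), attention: %s\n",
    object@baseWidth, object@inChannels,
    if (nzchar(att)) att else "none"))
})

#' TrainConfig: optimization settings
#'
#' Defaults follow the reference training recipe: Adam, batch size 2,
#' initial learning rate 0.001, weight decay 1e-4, 100 epochs.
#'
#' @slot batchSize samples per gradient step.
#' @slot lr learning rate.
#' @slot weightDecay L2 penalty coupled into the gradient.
#' @slot epochs maximum training epochs.
#' @slot maxIterations optional hard cap on gradient steps (NA = none).
#' @slot seed RNG seed for shuffling.
#' @slot threshold probability threshold for binarization.
#' @slot valFraction fraction of training data held out for checkpoint
#'   selection.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(batchSize = "integer", lr = "numeric",
                 weightDecay = "numeric", epochs = "integer",
                 maxIterations = "numeric", seed = "integer",
                 threshold = "numeric", valFraction = "numeric"),
  validity = function(object) {
    if (object@lr <= 0) return("lr must be > 0")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@threshold <= 0 || object@threshold >= 1)
      return("threshold must be in (0, 1)")
    TRUE
  })

#' Construct a TrainConfig
#'
#' @param batchSize samples per step (default 2).
#' @param lr learning rate (default 0.001).
#' @param weightDecay L2 penalty (default 1e-4).
#' @param epochs training epochs (default 100).
#' @param maxIterations optional cap on total gradient steps (default NA).
#' @param seed shuffle/init seed.
#' @param threshold binarization threshold (default 0.5).
#' @param valFraction validation fraction for checkpoint selection
#'   (default 0.2; set 0 to select on training loss).
#' @return a [TrainConfig-class] object.
#' @export
trainConfig <- function(batchSize = 2L, lr = 0.001, weightDecay = 1e-4,
                        epochs = 100L, maxIterations = NA_real_, seed = 0L,
                        threshold = 0.5, valFraction = 0.2) {
  new("TrainConfig", batchSize = as.integer(batchSize), lr = lr,
      weightDecay = weightDecay, epochs = as.integer(epochs),
      maxIterations = as.numeric(maxIterations), seed = as.integer(seed),
      threshold = threshold, valFraction = valFraction)
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: Adam, batch %d, lr %g, weight decay %g, %d epochs\n",
    object@batchSize, object@lr, object@weightDecay, object@epochs))
})

#' VesselNet: the assembled segmentation network
#'
#' Wraps the module tree (held in an environment, since parameters are
#' mutable state) together with its configuration and build seed.
#'
#' @slot config a [NetworkConfig-class].
#' @slot modules environment holding the module tree (`$tree`).
#' @slot seed build seed.
#' @exportClass VesselNet
setClass("VesselNet",
  representation(config = "NetworkConfig", modules = "environment",
                 seed = "integer"))

setMethod("show", "VesselNet", function(object) {
  cat(sprintf(
    "VesselNet: stage plan [7,6,5,4,4F,4F] / [7,6,5,4,4F], base width %d\n",
    object@config@baseWidth))
  cat(sprintf("  %d trainable parameters, %d attention gates, seed %d\n",
              parameterCount(object), countAttentionGates(object),
              object@seed))
})

#' NetworkOutput: fused and side probability maps
#'
#' @slot fused fused probability map `[H, W, 1, N]`, values in `[0, 1]`.
#' @slot side list of 6 side probability maps (decoder stages 1-5 and the
#'   deepest encoder), each `[H, W, 1, N]`.
#' @slot fusedLogit,sideLogits the pre-sigmoid maps.
#' @exportClass NetworkOutput
setClass("NetworkOutput",
  representation(fused = "array", side = "list", fusedLogit = "array",
                 sideLogits = "list"),
  validity = function(object) {
    rng <- range(object@fused, vapply(object@side, range, numeric(2)))
    if (rng[1] < 0 || rng[2] > 1) return("probabilities must be in [0, 1]")
    TRUE
  })

setMethod("show", "NetworkOutput", function(object) {
  d <- dim(object@fused)
  cat(sprintf(
    "NetworkOutput: fused %dx%d map (batch %d) + %d side maps, range [%.3f, %.3f]\n",
    d[1], d[2], d[4], length(object@side), min(object@fused),
    max(object@fused)))
})

#' @describeIn networkForward fused-map accessor
#' @param x a `NetworkOutput`.
#' @export
fusedMap <- function(x) x@fused

#' @describeIn networkForward side-map accessor
#' @export
sideMaps <- function(x) x@side
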