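## Fundus preprocessing: the green channel carries the strongest
## vessel/background contrast in color fundus photographs, CLAHE lifts
## local contrast inside the field of view, and a gamma transform tames
## artifacts. Fixed composition order: green -> normalize -> CLAHE -> gamma.

#' @importFrom EBImage clahe readImage writeImage
NULL

#' Preprocessing configuration
#'
#' @param claheClip CLAHE clip limit (default 2.0).
#' @param claheTiles contextual tile grid `c(nx, ny)` (default `c(8, 8)`).
#' @param gamma gamma exponent (default 1.2; > 1 darkens midtones).
#' @return a named list used by [preprocessSample()].
#' @export
preprocessConfig <- function(claheClip = 2.0, claheTiles = c(8L, 8L),
                             gamma = 1.2) {
  if (claheClip <= 0) stop("claheClip must be > 0")
  if (gamma <= 0) stop("gamma must be > 0")
  list(claheClip = claheClip, claheTiles = as.integer(claheTiles),
       gamma = gamma)
}

#' Extract the green channel and normalize to [0, 1]
#'
#' @param sample a [FundusSample-class]; the image may be RGB(A) or already
#'   grayscale, in `[0, 1]` or 8-bit.
#' @return the sample with a grayscale image matrix in `[0, 1]`; mask and
#'   FOV untouched.
#' @export
extractGreenNormalize <- function(sample) {
  img <- sample@image
  d <- dim(img)
  if (length(d) == 3L) {
    if (d[3] == 1L) img <- img[, , 1L]
    else if (d[3] %in% c(3L, 4L)) img <- img[, , 2L]
    else stop("expected 1, 3, or 4 channels, got ", d[3])
  }
  if (max(img) > 1) img <- img / 255
  img <- pmin(pmax(img, 0), 1)
  fundusSample(matrix(img, d[1], d[2]), sample@mask, sample@fov, sample@id)
}

#' Contrast-limited adaptive histogram equalization
#'
#' @param img single-channel matrix, values in `[0, 1]`.
#' @param claheClip clip limit.
#' @param claheTiles tile grid `c(nx, ny)`.
#' @return equalized matrix in `[0, 1]`, same size.
#' @export
claheEnhance <- function(img, claheClip = 2.0, claheTiles = c(8L, 8L)) {
  if (length(dim(img)) != 2L) stop("CLAHE needs a 2-D single-channel image")
  if (diff(range(img)) == 0) return(img) # degenerate histogram
  ## the tile grid must divide the image; mirror-pad to the next multiple
  ## and crop back
  d <- dim(img)
  H <- ceiling(d[1] / claheTiles[1]) * claheTiles[1]
  W <- ceiling(d[2] / claheTiles[2]) * claheTiles[2]
  pad <- img
  if (H > d[1]) pad <- rbind(pad, pad[d[1]:(2 * d[1] - H + 1), , drop = FALSE])
  if (W > d[2]) pad <- cbind(pad, pad[, d[2]:(2 * d[2] - W + 1), drop = FALSE])
  out <- clahe(pad, nx = claheTiles[1], ny = claheTiles[2],
               limit = claheClip)
  matrix(pmin(pmax(as.numeric(out[seq_len(d[1]), seq_len(d[2])]), 0), 1),
         d[1], d[2])
}

#' Gamma transform
#'
#' @param img matrix/array in `[0, 1]`.
#' @param gamma exponent (> 0); `img^gamma` elementwise.
#' @return transformed image, same shape.
#' @export
gammaCorrect <- function(img, gamma = 1.2) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (min(img) < 0 || max(img) > 1) stop("image must be in [0, 1]")
  img^gamma
}

#' Full preprocessing chain for one sample
#'
#' Applies, in order: green-channel extraction with normalization, CLAHE,
#' gamma correction.
#'
#' @param sample a [FundusSample-class].
#' @param config list from [preprocessConfig()].
#' @return the preprocessed [FundusSample-class].
#' @export
preprocessSample <- function(sample, config = preprocessConfig()) {
  s <- extractGreenNormalize(sample)
  img <- claheEnhance(matrix(s@image, dim(s@image)[1], dim(s@image)[2]),
                      config$claheClip, config$claheTiles)
  img <- gammaCorrect(img, config$gamma)
  fundusSample(img, s@mask, s@fov, s@id)
}
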