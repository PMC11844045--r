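## Synthetic fundus phantoms. A phantom emulates the structure of a fundus
## photograph — a circular field of view, a smooth radial background with
## sensor noise, and darker curvilinear vessel trees — with pixel-perfect
## ground truth, so every pipeline stage is testable without downloading a
## real dataset. Vessel trees are grown as seeded random walks from roots
## on the FOV rim: each unit step jitters the heading, stamps a disk of the
## current width, and may spawn a child branch whose width is scaled by the
## decay factor (children below 1 px are pruned). Disks stamped along unit
## steps overlap, so each tree's mask is 8-connected by construction.

stampDisk <- function(mask, r0, c0, radius, S) {
  ## a disk must always cover the pixel nearest its centre (which can be up
  ## to sqrt(1/2) away), or 1-px-wide branches would leave gaps
  radius <- max(radius, 0.72)
  rr <- max(1L, floor(r0 - radius)):min(S, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(S, ceiling(c0 + radius))
  if (!length(rr) || !length(cc)) return(mask)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  mask[rr, cc] <- mask[rr, cc] | (d2 <= radius^2)
  mask
}

#' Generate one synthetic fundus phantom
#'
#' @param spec a [PhantomSpec-class]; the result is fully determined by it
#'   (bitwise reproducible).
#' @return a [FundusSample-class] with the noisy image (8-bit quantized, as
#'   on disk), the exact vessel mask, and the circular FOV mask.
#' @examples
#' s <- generatePhantom(phantomSpec(seed = 1))
#' mean(sampleMask(s)[sampleFOV(s) == 1])
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    S <- spec@size
    ctr <- (S + 1) / 2
    R <- spec@fovRadiusFrac * S
    rr <- matrix(seq_len(S), S, S)
    cc <- t(rr)
    dist2 <- (rr - ctr)^2 + (cc - ctr)^2
    fov <- dist2 <= R^2
    ## background: bright center falling off toward the rim
    bg <- 0.45 + 0.3 * pmax(0, 1 - dist2 / R^2)
    mask <- matrix(FALSE, S, S)
    ## each branch: (row, col, heading, width, step budget). A branch ends
    ## when it leaves the FOV or exhausts its budget — roots get about two
    ## FOV radii of path, children a fraction of the parent's remainder —
    ## so trees taper and terminate the way retinal vessels do instead of
    ## filling the disk.
    queue <- vector("list", spec@nRoots)
    for (k in seq_len(spec@nRoots)) {
      th <- runif(1, 0, 2 * pi)
      queue[[k]] <- c(ctr + 0.95 * R * sin(th), ctr + 0.95 * R * cos(th),
                      th + pi + rnorm(1, 0, 0.2), spec@rootWidth,
                      round(1.9 * R))
    }
    while (length(queue)) {
      br <- queue[[1]]
      queue <- queue[-1]
      r <- br[1]; c <- br[2]; th <- br[3]; w <- br[4]
      budget <- br[5]
      for (step in seq_len(budget)) {
        if ((r - ctr)^2 + (c - ctr)^2 > R^2) break
        mask <- stampDisk(mask, r, c, w / 2, S)
        th <- th + rnorm(1, 0, spec@curvatureSigma)
        r <- r + sin(th)
        c <- c + cos(th)
        if (runif(1) < spec@branchProb && w * spec@widthDecay >= 1) {
          side <- sample(c(-1, 1), 1)
          queue <- c(queue, list(c(r, c, th + side * runif(1, 0.3, 0.9),
                                   w * spec@widthDecay,
                                   round(0.4 * (budget - step)))))
        }
      }
    }
    mask <- mask & fov
    img <- bg - spec@vesselContrast * mask +
      matrix(rnorm(S * S, 0, spec@noiseSigma), S, S)
    img <- img * fov
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 255) / 255 # match the 8-bit on-disk representation
    fundusSample(img, matrix(as.numeric(mask), S, S),
                 matrix(as.numeric(fov), S, S),
                 sprintf("phantom%03d", spec@seed))
  })
}

#' Generate a phantom dataset
#'
#' Generates `n` phantoms with consecutive seeds and, when `dir` is given,
#' writes them in the standard layout (`images/`, `masks/`, `fov/`,
#' `manifest.csv`).
#'
#' @param n number of phantoms (>= 1).
#' @param baseSeed seed of the first phantom; phantom k uses
#'   `baseSeed + k - 1`.
#' @param dir optional output directory.
#' @param ... overrides passed to [phantomSpec()] (e.g. `size = 64`).
#' @return list of [FundusSample-class] objects (invisibly when writing).
#' @export
generateDataset <- function(n, baseSeed = 0L, dir = NULL, ...) {
  if (n < 1L) stop("n must be >= 1")
  samples <- lapply(seq_len(n) - 1L, function(k)
    generatePhantom(phantomSpec(seed = baseSeed + k, ...)))
  if (!is.null(dir)) {
    writeFundusDataset(samples, dir)
    return(invisible(samples))
  }
  samples
}
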