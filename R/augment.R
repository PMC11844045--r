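## Augmentation bookkeeping. Flips multiply the set by exactly 4 (original,
## horizontal, vertical, both) and translations by exactly 5 (original plus
## one shift of magnitude t in each cardinal direction, zero-filled) — the
## multiplicities that take 40 source images to 160 and then 800, and 28 to
## 112 and then 560. Image, mask, and FOV always receive the identical
## geometric transform. Derived ids are `<id>__<tag>`, so the source image
## of any variant is the prefix before the first "__" (used by the
## leakage-safe split).

flip2d <- function(m, h, v) {
  if (is.null(m)) return(NULL)
  d <- dim(m)
  if (length(d) == 2L) {
    if (h) m <- m[, d[2]:1, drop = FALSE]
    if (v) m <- m[d[1]:1, , drop = FALSE]
  } else {
    if (h) m <- m[, d[2]:1, , drop = FALSE]
    if (v) m <- m[d[1]:1, , , drop = FALSE]
  }
  m
}

shift2d <- function(m, dr, dc) {
  if (is.null(m)) return(NULL)
  d <- dim(m)
  out <- array(0, d)
  rs <- intersect(seq_len(d[1]), seq_len(d[1]) + dr)
  cs <- intersect(seq_len(d[2]), seq_len(d[2]) + dc)
  if (length(d) == 2L) out[rs, cs] <- m[rs - dr, cs - dc]
  else out[rs, cs, ] <- m[rs - dr, cs - dc, ]
  if (is.matrix(m) || length(d) == 2L) matrix(out, d[1], d[2]) else out
}

applyGeom <- function(s, fimg, tag) {
  fundusSample(fimg(s@image),
               if (is.null(s@mask)) NULL else fimg(s@mask),
               if (is.null(s@fov)) NULL else fimg(s@fov),
               paste(s@id, tag, sep = "__"))
}

#' Flip augmentation (x4)
#'
#' Each sample yields exactly four: the original, its horizontal flip,
#' vertical flip, and combined flip, with image, mask, and FOV transformed
#' identically.
#'
#' @param samples list of [FundusSample-class] objects.
#' @return list of length `4 * length(samples)`, ids suffixed
#'   `__orig`, `__hf`, `__vf`, `__hvf`.
#' @export
augmentFlips <- function(samples) {
  if (!length(samples)) stop("empty input set")
  out <- vector("list", 4L * length(samples))
  i <- 0L
  for (s in samples) {
    out[[i + 1L]] <- applyGeom(s, identity, "orig")
    out[[i + 2L]] <- applyGeom(s, function(m) flip2d(m, TRUE, FALSE), "hf")
    out[[i + 3L]] <- applyGeom(s, function(m) flip2d(m, FALSE, TRUE), "vf")
    out[[i + 4L]] <- applyGeom(s, function(m) flip2d(m, TRUE, TRUE), "hvf")
    i <- i + 4L
  }
  out
}

#' Translation augmentation (x5)
#'
#' Each sample yields exactly five: the original plus shifts of magnitude
#' `t` pixels right, left, down, and up; vacated pixels are zero-filled in
#' image, mask, and FOV alike.
#'
#' @param samples list of [FundusSample-class] objects.
#' @param t translation magnitude in pixels (default 50); both image sides
#'   must exceed it.
#' @return list of length `5 * length(samples)`, ids suffixed `__t0`,
#'   `__txp`, `__txn`, `__typ`, `__tyn`.
#' @export
augmentTranslations <- function(samples, t = 50L) {
  if (!length(samples)) stop("empty input set")
  t <- as.integer(t)
  out <- vector("list", 5L * length(samples))
  i <- 0L
  for (s in samples) {
    d <- dim(s@image)
    if (d[1] <= t || d[2] <= t) stop("translation exceeds image")
    out[[i + 1L]] <- applyGeom(s, identity, "t0")
    out[[i + 2L]] <- applyGeom(s, function(m) shift2d(m, 0L, t), "txp")
    out[[i + 3L]] <- applyGeom(s, function(m) shift2d(m, 0L, -t), "txn")
    out[[i + 4L]] <- applyGeom(s, function(m) shift2d(m, t, 0L), "typ")
    out[[i + 5L]] <- applyGeom(s, function(m) shift2d(m, -t, 0L), "tyn")
    i <- i + 5L
  }
  out
}

#' Source id of a (possibly augmented) sample
#'
#' @param id sample id, e.g. `"img07__hf__txp"`.
#' @return the id prefix before the first `"__"`.
#' @export
sourceId <- function(id) sub("__.*$", "", id)

#' Leakage-safe train/test split
#'
#' Splits at the source-image level: all augmented variants of one source
#' image land on the same side, so no augmented copy of a test image leaks
#' into training. Targets `round(ratio * n)` training samples (exact when
#' all sources have the same number of variants).
#'
#' @param samples list of [FundusSample-class] objects (>= 5).
#' @param ratio training fraction (default 0.8, the 4:1 split).
#' @param seed integer seed; the split is reproducible.
#' @return list with elements `train` and `test`.
#' @export
splitDataset <- function(samples, ratio = 0.8, seed = 0L) {
  if (length(samples) < 5L) stop("need at least 5 samples to split")
  ids <- vapply(samples, sampleId, character(1))
  src <- sourceId(ids)
  sizes <- table(src)
  target <- round(ratio * length(samples))
  ord <- withSeed(seed, sample(names(sizes)))
  trainSrc <- character(0)
  count <- 0L
  for (s in ord) {
    if (abs(count + sizes[[s]] - target) <= abs(count - target)) {
      trainSrc <- c(trainSrc, s)
      count <- count + sizes[[s]]
    }
  }
  inTrain <- src %in% trainSrc
  list(train = samples[inTrain], test = samples[!inTrain])
}
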