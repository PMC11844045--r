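## Dataset directory layout (mirrors the public fundus benchmarks):
##   images/<id>.png   masks/<id>.png   fov/<id>.png   manifest.csv
## Images are written as 8-bit PNG; binary masks round-trip exactly.

#' Write a dataset of samples to a directory
#'
#' @param samples list of [FundusSample-class] objects.
#' @param dir target directory (created if missing).
#' @param split optional character vector (per sample) recorded in the
#'   manifest, e.g. `"train"` / `"test"`.
#' @return the manifest data frame (id, source, split, paths), invisibly.
#' @export
writeFundusDataset <- function(samples, dir, split = NULL) {
  for (sub in c("images", "masks", "fov"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(samples, sampleId, character(1))
  hasMask <- logical(length(samples))
  hasFov <- logical(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    writeImage(s@image, file.path(dir, "images", paste0(ids[i], ".png")),
               type = "png", bits.per.sample = 8L)
    if (!is.null(s@mask)) {
      hasMask[i] <- TRUE
      writeImage(s@mask, file.path(dir, "masks", paste0(ids[i], ".png")),
                 type = "png", bits.per.sample = 8L)
    }
    if (!is.null(s@fov)) {
      hasFov[i] <- TRUE
      writeImage(s@fov, file.path(dir, "fov", paste0(ids[i], ".png")),
                 type = "png", bits.per.sample = 8L)
    }
  }
  manifest <- data.frame(
    id = ids, source = sourceId(ids),
    split = if (is.null(split)) NA_character_ else split,
    image = file.path("images", paste0(ids, ".png")),
    mask = ifelse(hasMask, file.path("masks", paste0(ids, ".png")), NA),
    fov = ifelse(hasFov, file.path("fov", paste0(ids, ".png")), NA))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

readOneImage <- function(path) {
  a <- readImage(path)
  d <- dim(a)
  if (length(d) == 2L) matrix(as.numeric(a), d[1], d[2])
  else array(as.numeric(a), d)
}

#' Read a dataset directory
#'
#' Reads `images/`, and when present `masks/` and `fov/`, pairing files by
#' id from `manifest.csv` (or by filename when there is no manifest).
#'
#' @param dir dataset directory.
#' @param split optional split label; when given and the manifest records
#'   splits, only matching samples are read.
#' @return list of [FundusSample-class] objects.
#' @export
readFundusDataset <- function(dir, split = NULL) {
  mpath <- file.path(dir, "manifest.csv")
  if (file.exists(mpath)) {
    man <- read.csv(mpath, stringsAsFactors = FALSE)
    if (!is.null(split) && !all(is.na(man$split)))
      man <- man[man$split == split, , drop = FALSE]
    ids <- man$id
  } else {
    files <- list.files(file.path(dir, "images"), pattern = "\\.png$")
    ids <- sub("\\.png$", "", files)
  }
  if (!length(ids)) stop("empty dataset in ", dir)
  lapply(ids, function(id) {
    img <- readOneImage(file.path(dir, "images", paste0(id, ".png")))
    rd <- function(sub) {
      p <- file.path(dir, sub, paste0(id, ".png"))
      if (!file.exists(p)) return(NULL)
      m <- readOneImage(p)
      matrix(as.numeric(m > 0.5), nrow(m), ncol(m))
    }
    fundusSample(img, rd("masks"), rd("fov"), id)
  })
}
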