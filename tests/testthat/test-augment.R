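# Augmentation bookkeeping: exact multiplicities, transform consistency
# across image/mask/FOV, and the leakage-safe split.

test_that("flip augmentation multiplies the set by exactly 4", {
  forty <- lapply(1:40, function(i) dummySample(sprintf("im%02d", i), 64L, i))
  expect_length(augmentFlips(forty), 160L)
  expect_length(augmentFlips(forty[1:28]), 112L)
  expect_error(augmentFlips(list()), "empty")
})

test_that("translation augmentation multiplies the set by exactly 5", {
  forty <- lapply(1:40, function(i) dummySample(sprintf("im%02d", i), 64L, i))
  flipped <- augmentFlips(forty)
  expect_length(flipped, 160L)
  shifted <- augmentTranslations(flipped, t = 50L)
  expect_length(shifted, 800L)
  expect_length(augmentTranslations(flipped[1:112], t = 50L), 560L)
  small <- dummySample("small", 48L)
  expect_error(augmentTranslations(list(small), t = 50L),
               "translation exceeds image")
})

test_that("flips are involutions and act identically on all layers", {
  s <- dummySample("coord", 16L, 5)
  # coordinate-encoded image: value identifies the pixel
  s@image <- array(outer(1:16, 1:16, function(r, c) (r + 16 * c) / 300),
                   c(16, 16))
  s@mask <- matrix(as.numeric(outer(1:16, 1:16, `+`) %% 2L == 0L), 16, 16)
  out <- augmentFlips(list(s))
  ids <- vapply(out, sampleId, character(1))
  expect_identical(ids, paste0("coord__", c("orig", "hf", "vf", "hvf")))
  hf <- out[[2]]
  # double flip restores the original
  hf2 <- augmentFlips(list(hf))[[2]]
  expect_equal(hf2@image, s@image)
  expect_equal(hf2@mask, s@mask)
  # the image and mask moved together: flipped image col j = original col W+1-j
  expect_equal(hf@image[, 1], s@image[, 16])
  expect_equal(hf@mask[, 1], s@mask[, 16])
  expect_equal(hf@fov, s@fov)
})

test_that("translations zero-fill and compose back to identity centrally", {
  s <- dummySample("t", 64L, 6)
  t <- 10L
  out <- augmentTranslations(list(s), t = t)
  expect_length(out, 5L)
  right <- out[[2]] # shift +t along columns
  expect_equal(right@image[, (t + 1):64], s@image[, 1:(64 - t)])
  expect_true(all(right@image[, 1:t] == 0))
  expect_true(all(right@mask[, 1:t] == 0))
  expect_true(all(right@fov[, 1:t] == 0))
  # +t then -t restores the unvacated region
  back <- augmentTranslations(list(right), t = t)[[3]]
  expect_equal(back@image[, 1:(64 - t)], s@image[, 1:(64 - t)])
})

test_that("split is grouped by source, disjoint, and reproducible", {
  forty <- lapply(1:40, function(i) dummySample(sprintf("im%02d", i), 52L, i))
  full <- augmentTranslations(augmentFlips(forty), t = 50L)
  expect_length(full, 800L)
  sp <- splitDataset(full, ratio = 0.8, seed = 3)
  expect_length(sp$train, 640L)
  expect_length(sp$test, 160L)
  trainSrc <- unique(sourceId(vapply(sp$train, sampleId, character(1))))
  testSrc <- unique(sourceId(vapply(sp$test, sampleId, character(1))))
  expect_length(intersect(trainSrc, testSrc), 0L)
  # all 20 variants of each source are on one side
  counts <- table(sourceId(vapply(sp$train, sampleId, character(1))))
  expect_true(all(counts == 20L))
  sp2 <- splitDataset(full, ratio = 0.8, seed = 3)
  expect_identical(vapply(sp2$train, sampleId, character(1)),
                   vapply(sp$train, sampleId, character(1)))
  expect_error(splitDataset(full[1:3]), "at least 5")
})
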