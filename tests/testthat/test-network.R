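# Assembled network: stage plan, seeded builds, shape/range contracts,
# fusion linearity, checkpoint round trip, gradient finiteness.

test_that("stage registry follows the fixed plan", {
  net <- buildNetwork(networkConfig(baseWidth = 4), seed = 1)
  tree <- net@modules$tree
  expect_identical(vapply(tree$en, function(b) b$depth, integer(1)),
                   c(7L, 6L, 5L, 4L, 4L, 4L))
  expect_identical(vapply(tree$en, function(b) isTRUE(b$dilated), logical(1)),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(vapply(tree$de, function(b) b$depth, integer(1)),
                   c(7L, 6L, 5L, 4L, 4L))
  expect_identical(vapply(tree$de, function(b) isTRUE(b$dilated), logical(1)),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # gates: non-dilated DARSU-L has L-2, the dilated variant 3
  expect_identical(countAttentionGates(net),
                   sum(c(5L, 4L, 3L, 2L, 3L, 3L), c(5L, 4L, 3L, 2L, 3L)))
})

test_that("builds are reproducible from the seed and widths scale", {
  n1 <- buildNetwork(networkConfig(baseWidth = 4), seed = 11)
  n2 <- buildNetwork(networkConfig(baseWidth = 4), seed = 11)
  p1 <- darsunet:::collectParams(n1@modules$tree)
  p2 <- darsunet:::collectParams(n2@modules$tree)
  expect_identical(lapply(p1, function(p) p$v), lapply(p2, function(p) p$v))
  counts <- vapply(c(4L, 8L, 16L), function(bw)
    parameterCount(buildNetwork(networkConfig(baseWidth = bw), seed = 1)),
    numeric(1))
  expect_true(all(diff(counts) > 0))
  expect_error(networkConfig(baseWidth = 1), "baseWidth")
})

test_that("forward shapes, probability ranges, and size validation", {
  net <- buildNetwork(networkConfig(baseWidth = 2), seed = 2)
  out <- networkForward(net, array(runif(64 * 64), c(64, 64, 1, 1)))
  expect_identical(dim(fusedMap(out)), c(64L, 64L, 1L, 1L))
  expect_length(sideMaps(out), 6L)
  for (m in sideMaps(out)) expect_identical(dim(m), c(64L, 64L, 1L, 1L))
  expect_true(all(fusedMap(out) >= 0 & fusedMap(out) <= 1))
  out96 <- networkForward(net, array(runif(96 * 96), c(96, 96, 1, 1)))
  expect_identical(dim(fusedMap(out96)), c(96L, 96L, 1L, 1L))
  expect_error(networkForward(net, array(0.5, c(70, 70, 1, 1))),
               "multiple of 32")
})

test_that("mean-weight fusion makes the fused logit the side-logit mean", {
  net <- buildNetwork(networkConfig(baseWidth = 2), seed = 3)
  fuse <- net@modules$tree$fuse
  fuse$w$v[] <- 1 / 6
  fuse$b$v[] <- 0
  out <- networkForward(net, array(runif(64 * 64), c(64, 64, 1, 1)))
  sideMean <- Reduce(`+`, out@sideLogits) / 6
  expect_equal(out@fusedLogit, sideMean, tolerance = 1e-6)
})

test_that("checkpoints round-trip to a bitwise-equal forward", {
  net <- buildNetwork(networkConfig(baseWidth = 2), seed = 4)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  before <- fusedMap(networkForward(net, x))
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(net, path)
  net2 <- loadCheckpoint(path)
  expect_identical(fusedMap(networkForward(net2, x)), before)
  expect_error(suppressWarnings(loadCheckpoint(tempfile())),
               "corrupt checkpoint")
  unlink(path)
})

test_that("every parameter receives a finite gradient", {
  net <- buildNetwork(networkConfig(baseWidth = 2), seed = 5)
  tree <- net@modules$tree
  set.seed(6)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  y <- array(rbinom(64 * 64, 1, 0.1), c(64, 64, 1, 1))
  logits <- darsunet:::netForwardT(tree, darsunet:::agTensor(x),
                                   training = TRUE)
  loss <- darsunet:::combinedLossT(logits, y)
  darsunet:::agBackward(loss)
  params <- darsunet:::collectParams(tree)
  ok <- vapply(params, function(p)
    !is.null(p$grad) && all(is.finite(p$grad)), logical(1))
  expect_true(all(ok))
})

test_that("evaluation forward is bitwise repeatable", {
  net <- buildNetwork(networkConfig(baseWidth = 2), seed = 7)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  expect_identical(fusedMap(networkForward(net, x)),
                   fusedMap(networkForward(net, x)))
})
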