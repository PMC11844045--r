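# DARSU block contracts: shapes, gate counts, divisibility, the residual
# connection, the dilated variant's constant spatial size and receptive
# field, ablation toggles, determinism.

test_that("conv+BN+ReLU unit honours its contracts", {
  w <- initConvUnit(2, 3, seed = 1)
  x <- rfm(8, 8, 2, 1, seed = 2)
  out <- convBNReLU(x, w)
  expect_identical(dim(out), c(8L, 8L, 3L, 1L))
  expect_true(all(out >= 0))
  out8 <- convBNReLU(x, w, dilation = 8)
  expect_identical(dim(out8), c(8L, 8L, 3L, 1L))
  expect_error(convBNReLU(rfm(8, 8, 3, 1), w), "channel mismatch")
  # identity BN in eval mode + centred delta kernel x2: pure doubling
  wid <- initConvUnit(1, 1)
  wid$w[] <- 0
  wid$w[2, 2, 1, 1] <- 2
  wid$b <- 0
  out <- convBNReLU(array(3, c(5, 5, 1, 1)), wid)
  # tolerance covers BN's variance epsilon: 6 / sqrt(1 + 1e-5)
  expect_equal(as.numeric(out), rep(6, 25), tolerance = 1e-4)
})

test_that("DARSU-L shape contract and divisibility rule", {
  blk <- darsuBlock(7, 3, 4, 8, seed = 1)
  out <- darsuForward(blk, rfm(64, 64, 3, 1, seed = 2))
  expect_identical(dim(out), c(64L, 64L, 8L, 1L))
  b4 <- darsuBlock(4, 1, 2, 2, seed = 1)
  expect_identical(dim(darsuForward(b4, rfm(8, 8, 1, 1))), c(8L, 8L, 2L, 1L))
  expect_error(darsuForward(b4, rfm(6, 6, 1, 1)), "divisible")
})

test_that("DARSU-L contains exactly L - 2 attention gates", {
  for (L in 4:7)
    expect_identical(countAttentionGates(darsuBlock(L, 1, 2, 2, seed = 1)),
                     L - 2L)
})

test_that("residual connection: zeroed U-path leaves exactly f0", {
  blk <- darsuBlock(4, 2, 2, 3, seed = 3)
  # zero every parameter except the stage-input projection f0
  params <- darsunet:::collectParams(blk)
  for (nm in names(params)) {
    if (!startsWith(nm, "f0")) params[[nm]]$v <- 0 * params[[nm]]$v
  }
  x <- rfm(8, 8, 2, 1, seed = 4)
  out <- darsuForward(blk, x)
  f0 <- convBNReLU(x, list(w = blk$f0$conv$w$v, b = blk$f0$conv$b$v,
                           gamma = blk$f0$bn$gamma$v, beta = blk$f0$bn$beta$v,
                           runMean = blk$f0$bn$state$rm,
                           runVar = blk$f0$bn$state$rv))
  expect_equal(out, f0, tolerance = 1e-12)
})

test_that("dilated variant keeps spatial size at every internal layer", {
  b <- darsuBlock(4, 2, 3, 4, dilated = TRUE, seed = 5)
  sizes <- darsuLayerSizes(b, rfm(16, 16, 2, 1, seed = 6))
  expect_true(all(vapply(sizes, function(s) all(s == c(16L, 16L)),
                         logical(1))))
  out <- darsuForward(b, rfm(16, 16, 2, 1, seed = 6))
  expect_identical(dim(out), c(16L, 16L, 4L, 1L))
})

test_that("dilated encoder chain has a 31-pixel receptive field", {
  b <- darsuBlock(4, 2, 2, 2, dilated = TRUE, seed = 7)
  expect_identical(dilatedReceptiveField(b, 64L), 31L)
})

test_that("attention ablation reduces to a plain residual U-block", {
  off <- list(gate = FALSE, sam = FALSE, cam = FALSE)
  for (spec in list(list(L = 5, dil = FALSE), list(L = 4, dil = TRUE))) {
    blk <- darsuBlock(spec$L, 1, 2, 2, dilated = spec$dil, attention = off,
                      seed = 8)
    out <- darsuForward(blk, rfm(16, 16, 1, 1, seed = 9))
    expect_identical(dim(out), c(16L, 16L, 2L, 1L))
  }
})

test_that("evaluation-mode forwards are bitwise repeatable", {
  blk <- darsuBlock(5, 2, 3, 4, seed = 10)
  x <- rfm(16, 16, 2, 2, seed = 11)
  expect_identical(darsuForward(blk, x), darsuForward(blk, x))
})
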