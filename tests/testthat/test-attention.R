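# The three attention primitives against scalar straight-line oracles,
# plus their shape/range/linearity contracts.

test_that("attention gate matches hand arithmetic on scalar input", {
  # x = g = 2, all kernel weights 1, biases 0, fint = 1:
  # pre-activation ReLU(2 + 2) = 4, alpha = sigmoid(4), out = 2 * sigmoid(4)
  w <- list(wx = array(1, c(1, 1, 1, 1)), bx = 0,
            wg = array(1, c(1, 1, 1, 1)), bg = 0,
            psi = array(1, c(1, 1, 1, 1)), bpsi = 0)
  out <- attentionGate(array(2, c(1, 1, 1, 1)), array(2, c(1, 1, 1, 1)), w)
  expect_equal(as.numeric(out), 2 * plogis(4), tolerance = 1e-10)
  expect_equal(round(as.numeric(out), 4), 1.9640)
})

test_that("all three operators match 1x1 oracles with random weights", {
  for (seed in 1:5) {
    set.seed(seed)
    C <- sample(2:6, 1)
    xv <- rnorm(C)
    gv <- rnorm(C)
    wg <- initAttentionGate(C, C, seed = seed + 10)
    got <- attentionGate(array(xv, c(1, 1, C, 1)), array(gv, c(1, 1, C, 1)), wg)
    expect_equal(as.numeric(got), oracleGate1x1(xv, gv, wg), tolerance = 1e-6)

    ws <- initSpatialAttention(7, seed = seed + 20)
    got <- spatialAttention(array(xv, c(1, 1, C, 1)), ws)
    expect_equal(as.numeric(got), oracleSAM1x1(xv, ws), tolerance = 1e-6)

    wc <- initChannelAttention(C, reduction = 2, seed = seed + 30)
    got <- channelAttention(array(xv, c(1, 1, C, 1)), wc)
    expect_equal(as.numeric(got), oracleCAM1x1(xv, wc), tolerance = 1e-6)
  }
})

test_that("zero-weight configurations give the exact sigmoid(0) = 0.5 scaling", {
  x <- rfm(4, 4, 2, 1, seed = 2)
  wg <- initAttentionGate(2, 2, seed = 1)
  wg$psi[] <- 0; wg$bpsi <- 0
  expect_equal(attentionGate(x, x, wg), 0.5 * x, tolerance = 1e-12,
               ignore_attr = TRUE)
  ws <- initSpatialAttention(7, seed = 1)
  ws$w[] <- 0; ws$b <- 0
  expect_equal(spatialAttention(x, ws), 0.5 * x, tolerance = 1e-12,
               ignore_attr = TRUE)
  wc <- initChannelAttention(2, 2, seed = 1)
  wc$w2[] <- 0; wc$b2[] <- 0
  expect_equal(channelAttention(x, wc), 0.5 * x, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("operators preserve shape and coefficients stay in (0, 1)", {
  set.seed(99)
  for (hw in c(8L, 16L, 32L)) {
    B <- sample(1:2, 1); C <- sample(1:8, 1)
    x <- array(rnorm(hw * hw * C * B), c(hw, hw, C, B))
    g <- array(rnorm((hw / 2)^2 * C * B), c(hw / 2, hw / 2, C, B))
    wg <- initAttentionGate(C, C, seed = hw)
    out <- attentionGate(x, g, wg)
    expect_identical(dim(out), dim(x))
    a <- attr(out, "alpha")
    expect_true(all(a > 0 & a < 1))
    out <- spatialAttention(x, initSpatialAttention(7, seed = hw))
    expect_identical(dim(out), dim(x))
    expect_true(all(attr(out, "alpha") > 0 & attr(out, "alpha") < 1))
    out <- channelAttention(x, initChannelAttention(C, seed = hw))
    expect_identical(dim(out), dim(x))
    expect_true(all(attr(out, "alpha") > 0 & attr(out, "alpha") < 1))
  }
})

test_that("gating is exactly linear in x for fixed coefficients", {
  x <- rfm(6, 6, 3, 2, seed = 4)
  w <- initSpatialAttention(7, seed = 5)
  out <- spatialAttention(x, w)
  a <- attr(out, "alpha")
  # output must be alpha * x elementwise (alpha broadcast over channels)
  expect_equal(as.numeric(out),
               as.numeric(x * darsunet:::bcastTo(a, dim(x))),
               tolerance = 1e-12)
  # scaling x with frozen alpha scales the output
  expect_equal(3 * as.numeric(out),
               as.numeric((3 * x) * darsunet:::bcastTo(a, dim(x))),
               tolerance = 1e-12)
})

test_that("input contract violations error out", {
  w <- initAttentionGate(2, 2, seed = 1)
  x <- rfm(8, 8, 2, 2)
  expect_error(attentionGate(x, rfm(4, 4, 2, 1), w), "batch mismatch")
  expect_error(attentionGate(x, rfm(3, 3, 2, 2), w),
               "incompatible gate resolution")
  expect_error(initSpatialAttention(6), "odd")
  expect_error(initChannelAttention(4, reduction = 0), "reduction")
})
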