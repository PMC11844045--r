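# Gradient correctness of the feature-map engine: every primitive's
# analytic backward pass must agree with central finite differences.

agt <- function(v) darsunet:::agTensor(v, requires = TRUE)

scalarLossOf <- function(op) {
  # wraps op into scalar-valued function + its analytic input gradient
  function(x0, ...) {
    xt <- agt(x0)
    out <- op(xt, ...)
    loss <- darsunet:::agSumAll(darsunet:::agSigmoid(out))
    darsunet:::agBackward(loss)
    list(fn = function(xx) {
      t2 <- darsunet:::agTensor(xx)
      sum(1 / (1 + exp(-op(t2, ...)$v)))
    }, gan = xt$grad)
  }
}

test_that("convolution gradients match finite differences (incl. dilation)", {
  x <- rfm(6, 5, 2, 2, seed = 3)
  w <- agt(array(rnorm(3 * 3 * 2 * 3, sd = 0.4), c(3, 3, 2, 3)))
  b <- agt(rnorm(3))
  for (dil in c(1L, 2L)) {
    r <- scalarLossOf(function(t) darsunet:::agConv2d(t, w, b, dil))(x)
    expectGradMatches(r$fn, x, r$gan)
  }
  # weight and bias gradients (fresh tensors so nothing has accumulated)
  w2 <- agt(w$v)
  b2 <- agt(b$v)
  out <- darsunet:::agConv2d(darsunet:::agTensor(x), w2, b2, 1L)
  darsunet:::agBackward(darsunet:::agSumAll(darsunet:::agSigmoid(out)))
  fnw <- function(ww) {
    sum(1 / (1 + exp(-darsunet:::cpp_conv2d(x, ww, b2$v, 1L))))
  }
  expectGradMatches(fnw, w2$v, w2$grad)
  fnb <- function(bb) {
    sum(1 / (1 + exp(-darsunet:::cpp_conv2d(x, w2$v, bb, 1L))))
  }
  expectGradMatches(fnb, b2$v, b2$grad)
})

test_that("pooling, resize, and elementwise gradients check out", {
  x <- rfm(6, 4, 2, 1, seed = 5)
  r <- scalarLossOf(darsunet:::agMaxPool2)(x)
  expectGradMatches(r$fn, x, r$gan)
  r <- scalarLossOf(function(t) darsunet:::agUpsample(t, 9L, 7L))(x)
  expectGradMatches(r$fn, x, r$gan)
  r <- scalarLossOf(darsunet:::agRelu)(x)
  expectGradMatches(r$fn, x, r$gan)
  r <- scalarLossOf(darsunet:::agChannelMean)(x)
  expectGradMatches(r$fn, x, r$gan)
  r <- scalarLossOf(darsunet:::agChannelMax)(x)
  expectGradMatches(r$fn, x, r$gan)
  r <- scalarLossOf(darsunet:::agGlobalMean)(x)
  expectGradMatches(r$fn, x, r$gan)
  r <- scalarLossOf(darsunet:::agGlobalMax)(x)
  expectGradMatches(r$fn, x, r$gan)
})

test_that("broadcast multiply gradients flow to both factors", {
  x <- rfm(4, 4, 3, 2, seed = 7)
  a <- abs(rfm(4, 4, 1, 2, seed = 8)) # spatial coefficient map
  xt <- agt(x); at <- agt(a)
  out <- darsunet:::agMulB(xt, at)
  darsunet:::agBackward(darsunet:::agSumAll(out))
  fnx <- function(xx) sum(darsunet:::agMulB(darsunet:::agTensor(xx),
                                            darsunet:::agTensor(a))$v)
  expectGradMatches(fnx, x, xt$grad)
  fna <- function(aa) sum(darsunet:::agMulB(darsunet:::agTensor(x),
                                            darsunet:::agTensor(aa))$v)
  expectGradMatches(fna, a, at$grad)
  # channel-vector broadcast
  cv <- abs(rfm(1, 1, 3, 2, seed = 9))
  ct <- agt(cv); xt2 <- agt(x)
  out2 <- darsunet:::agMulB(xt2, ct)
  darsunet:::agBackward(darsunet:::agSumAll(out2))
  fnc <- function(cc) sum(darsunet:::agMulB(darsunet:::agTensor(x),
                                            darsunet:::agTensor(cc))$v)
  expectGradMatches(fnc, cv, ct$grad)
})

test_that("batch normalization gradients are exact in both modes", {
  x <- rfm(4, 4, 2, 2, seed = 11)
  bn <- darsunet:::newBN(2L)
  bn$gamma$v <- c(1.3, 0.7)
  bn$beta$v <- c(0.1, -0.2)
  for (training in c(TRUE, FALSE)) {
    st0 <- list(rm = bn$state$rm, rv = bn$state$rv)
    xt <- agt(x)
    out <- darsunet:::agBatchNorm(xt, bn$gamma, bn$beta, bn$state, training)
    darsunet:::agBackward(darsunet:::agSumAll(darsunet:::agSigmoid(out)))
    gan <- xt$grad
    fn <- function(xx) {
      bn$state$rm <- st0$rm; bn$state$rv <- st0$rv
      o <- darsunet:::agBatchNorm(darsunet:::agTensor(xx), bn$gamma,
                                  bn$beta, bn$state, training)
      sum(1 / (1 + exp(-o$v)))
    }
    expectGradMatches(fn, x, gan, tol = 5e-4)
    bn$state$rm <- st0$rm; bn$state$rv <- st0$rv
  }
})

test_that("loss node gradients match finite differences", {
  set.seed(13)
  y <- array(rbinom(32, 1, 0.4), c(4, 4, 2, 1))
  p0 <- array(runif(32, 0.05, 0.95), c(4, 4, 2, 1))
  for (mk in list(function(t) darsunet:::agDiceLoss(t, y),
                  function(t) darsunet:::agBCELoss(t, y))) {
    pt <- agt(p0)
    loss <- mk(pt)
    darsunet:::agBackward(loss)
    fn <- function(pp) mk(darsunet:::agTensor(pp))$v
    expectGradMatches(fn, p0, pt$grad)
  }
})

test_that("gradients accumulate correctly through a shared node (diamond)", {
  x <- rfm(2, 2, 1, 1, seed = 17)
  xt <- agt(x)
  h <- darsunet:::agSigmoid(xt)
  out <- darsunet:::agAdd(h, h) # h feeds two consumers
  darsunet:::agBackward(darsunet:::agSumAll(out))
  s <- 1 / (1 + exp(-x))
  expect_equal(xt$grad, 2 * s * (1 - s), tolerance = 1e-12)
})
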