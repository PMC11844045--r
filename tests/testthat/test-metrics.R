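# Confusion counting and metric arithmetic.

test_that("confusion counts on a constructed 10x10 grid", {
  y <- matrix(0, 10, 10)
  y[1, 1:10] <- 1 # 10 foreground pixels
  pred <- matrix(0, 10, 10)
  pred[1, 1:8] <- 1 # hits 8 of them
  pred[5, 1:5] <- 1 # 5 false alarms
  cc <- confusionCounts(pred, y)
  expect_equal(cc, c(TP = 8, FP = 5, TN = 85, FN = 2))
  expect_equal(sum(cc), 100)
  # degenerate directions
  expect_equal(confusionCounts(y, y)[c("FP", "FN")], c(FP = 0, FN = 0))
  expect_equal(confusionCounts(1 - y, y)[c("TP", "TN")], c(TP = 0, TN = 0))
})

test_that("metric values on the hand-derived counts", {
  m <- computeMetrics(c(TP = 8, FN = 2, FP = 5, TN = 85))
  expect_equal(m[["Acc"]], 0.93, tolerance = 1e-12)
  expect_equal(m[["SE"]], 0.80, tolerance = 1e-12)
  expect_equal(m[["SP"]], 85 / 90, tolerance = 1e-12)
  expect_equal(m[["F1"]], 16 / 23, tolerance = 1e-12)
  expect_equal(m[["MIoU"]], 0.5 * (8 / 15 + 85 / 92), tolerance = 1e-12)
})

test_that("perfect predictions score 1 and class swap exchanges SE/SP", {
  set.seed(4)
  y <- matrix(rbinom(100, 1, 0.3), 10, 10)
  m <- computeMetrics(confusionCounts(y, y))
  expect_equal(unname(m), rep(1, 5))
  pred <- matrix(rbinom(100, 1, 0.4), 10, 10)
  m1 <- computeMetrics(confusionCounts(pred, y))
  m2 <- computeMetrics(confusionCounts(1 - pred, 1 - y))
  expect_equal(m1[["SE"]], m2[["SP"]], tolerance = 1e-12)
  expect_equal(m1[["SP"]], m2[["SE"]], tolerance = 1e-12)
  expect_equal(m1[["Acc"]], m2[["Acc"]], tolerance = 1e-12)
  expect_equal(m1[["MIoU"]], m2[["MIoU"]], tolerance = 1e-12)
})

test_that("metrics agree with a brute-force per-pixel recount", {
  set.seed(5)
  for (i in 1:25) {
    y <- matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16, 16)
    pred <- matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16, 16)
    got <- computeMetrics(confusionCounts(pred, y))
    expect_equal(got, oracleMetrics(as.numeric(pred), as.numeric(y)),
                 tolerance = 1e-12)
  }
})

test_that("FOV masking restricts the evaluated pixels", {
  y <- matrix(1, 4, 4)
  pred <- matrix(0, 4, 4)
  pred[1:2, ] <- 1
  fov <- matrix(0, 4, 4)
  fov[1:2, ] <- 1
  expect_equal(confusionCounts(pred, y, fov),
               c(TP = 8, FP = 0, TN = 0, FN = 0))
})

test_that("degenerate denominators warn and yield 0", {
  w <- capture_warnings(
    m <- computeMetrics(c(TP = 0, FP = 0, TN = 10, FN = 0)))
  expect_match(w, "degenerate", all = TRUE)
  expect_identical(m[["SE"]], 0)
  expect_error(computeMetrics(c(TP = -1, FP = 0, TN = 1, FN = 0)),
               "non-negative")
})
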