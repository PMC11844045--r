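# Independent straight-line oracles used to cross-check the package's
# vectorized / C++ implementations on tiny inputs.

# Attention gate on a 1x1-spatial input, plain scalar arithmetic over
# channel vectors. xv, gv: channel vectors; w: weight list as used by
# attentionGate().
oracleGate1x1 <- function(xv, gv, w) {
  fint <- dim(w$wx)[4]
  pre <- numeric(fint)
  for (f in seq_len(fint))
    pre[f] <- sum(w$wx[1, 1, , f] * xv) + w$bx[f] +
      sum(w$wg[1, 1, , f] * gv) + w$bg[f]
  act <- pmax(pre, 0)
  alpha <- 1 / (1 + exp(-(sum(w$psi[1, 1, , 1] * act) + w$bpsi)))
  xv * alpha
}

# SAM on a 1x1-spatial input: only the kernel centre tap touches the data.
oracleSAM1x1 <- function(xv, w) {
  k <- dim(w$w)[1]
  ctr <- (k + 1) / 2
  pre <- w$w[ctr, ctr, 1, 1] * mean(xv) + w$w[ctr, ctr, 2, 1] * max(xv) + w$b
  xv / (1 + exp(-pre))
}

# CAM on a 1x1-spatial input: mean-pool and max-pool vectors coincide.
oracleCAM1x1 <- function(xv, w) {
  cr <- dim(w$w1)[4]
  branch <- function(v) {
    hid <- pmax(vapply(seq_len(cr), function(f)
      sum(w$w1[1, 1, , f] * v) + w$b1[f], numeric(1)), 0)
    vapply(seq_along(v), function(c)
      sum(w$w2[1, 1, , c] * hid) + w$b2[c], numeric(1))
  }
  pre <- branch(xv) + branch(xv) # mean branch + max branch, equal at 1x1
  xv / (1 + exp(-pre))
}

# Brute-force per-pixel metric recount.
oracleMetrics <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    else fn <- fn + 1
  }
  tot <- tp + fp + tn + fn
  c(Acc = (tp + tn) / tot, SE = tp / (tp + fn), SP = tn / (tn + fp),
    F1 = 2 * tp / (2 * tp + fp + fn),
    MIoU = 0.5 * (tp / (tp + fp + fn) + tn / (tn + fn + fp)))
}

# Central finite-difference gradient at a handful of coordinates.
# fn: function(array) -> scalar; gan: analytic gradient array.
expectGradMatches <- function(fn, x, gan, n = 6, eps = 1e-5, tol = 1e-4) {
  set.seed(42)
  for (k in sample(length(x), min(n, length(x)))) {
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    fd <- (fn(xp) - fn(xm)) / (2 * eps)
    expect_equal(gan[k], fd, tolerance = tol,
                 label = sprintf("analytic grad at [%d]", k))
  }
}

# 8-connected flood fill: is the foreground of a binary matrix connected?
isConnected8 <- function(m) {
  idx <- which(m == 1, arr.ind = TRUE)
  if (!nrow(idx)) return(TRUE)
  lab <- matrix(FALSE, nrow(m), ncol(m))
  q <- list(idx[1, ])
  lab[idx[1, 1], idx[1, 2]] <- TRUE
  while (length(q)) {
    p <- q[[1]]; q <- q[-1]
    for (dr in -1:1) for (dc in -1:1) {
      r <- p[1] + dr; c <- p[2] + dc
      if (r >= 1 && c >= 1 && r <= nrow(m) && c <= ncol(m) &&
          m[r, c] == 1 && !lab[r, c]) {
        lab[r, c] <- TRUE
        q <- c(q, list(c(r, c)))
      }
    }
  }
  sum(lab) == sum(m)
}

# Small deterministic feature map.
rfm <- function(h, w, c, n, seed = 1) {
  set.seed(seed)
  array(rnorm(h * w * c * n), c(h, w, c, n))
}

# Tiny dummy sample for augmentation bookkeeping tests.
dummySample <- function(id, side = 64L, seed = 0L) {
  set.seed(seed)
  img <- matrix(runif(side * side), side, side)
  msk <- matrix(as.numeric(matrix(runif(side * side), side, side) > 0.9),
                side, side)
  fundusSample(img, msk, matrix(1, side, side), id)
}
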