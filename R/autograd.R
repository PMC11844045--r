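## Minimal reverse-mode autodiff over 4-D feature maps.
##
## A tensor is an environment holding a value (`v`, an array [H,W,C,N] or a
## scalar), an accumulated gradient (`grad`), and — when it was produced by an
## operation while gradients are enabled — its parent tensors plus a closure
## that maps the incoming gradient to per-parent gradients. Backpropagation is
## an iterative depth-first topological sort over that tape (the graphs here
## are several hundred nodes deep, too deep for recursion).

.ag <- new.env(parent = emptyenv())
.ag$grad_on <- TRUE
.ag$id <- 0L

agTensor <- function(v, requires = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$parents <- NULL
  e$backfn <- NULL
  e$requires <- requires
  .ag$id <- .ag$id + 1L
  e$id <- .ag$id
  class(e) <- "agTensor"
  e
}

is.agTensor <- function(x) inherits(x, "agTensor")

## Evaluate `expr` without recording the tape (evaluation mode).
agNoGrad <- function(expr) {
  old <- .ag$grad_on
  .ag$grad_on <- FALSE
  on.exit(.ag$grad_on <- old)
  expr
}

## Create a node; the tape is only recorded when some parent requires grad.
agNode <- function(v, parents, backfn) {
  if (.ag$grad_on &&
      any(vapply(parents, function(p) isTRUE(p$requires), logical(1)))) {
    t <- agTensor(v, requires = TRUE)
    t$parents <- parents
    t$backfn <- backfn
    t
  } else {
    agTensor(v)
  }
}

zerosLike <- function(v) {
  z <- array(0, if (is.null(dim(v))) length(v) else dim(v))
  if (is.null(dim(v))) as.vector(z) else z
}

agAccum <- function(t, g) {
  t$grad <- if (is.null(t$grad)) g else t$grad + g
  invisible(t)
}

## Reverse pass from a scalar (or any) tensor. Seeds with 1.
agBackward <- function(root) {
  ## iterative post-order DFS
  order <- vector("list", 256L)
  n_ord <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = root, i = 0L))
  assign(as.character(root$id), TRUE, envir = visited)
  while (length(stack)) {
    top <- stack[[length(stack)]]
    node <- top$node
    kids <- node$parents
    if (top$i < length(kids)) {
      stack[[length(stack)]]$i <- top$i + 1L
      child <- kids[[top$i + 1L]]
      key <- as.character(child$id)
      if (child$requires && !exists(key, envir = visited, inherits = FALSE)) {
        assign(key, TRUE, envir = visited)
        stack[[length(stack) + 1L]] <- list(node = child, i = 0L)
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  root$grad <- if (is.null(dim(root$v))) rep(1, length(root$v)) else
    array(1, dim(root$v))
  for (k in seq(n_ord, 1L)) {
    node <- order[[k]]
    if (is.null(node$backfn)) next
    gs <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (p$requires && !is.null(gs[[j]])) agAccum(p, gs[[j]])
    }
  }
  invisible(root)
}

agZeroGrad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

## ---- broadcasting helpers (value-level) -------------------------------

## Expand `a` to dims d, where a is [H,W,1,N] (spatial map) or [1,1,C,N]
## (per-channel weights).
bcastTo <- function(a, d) {
  da <- dim(a)
  if (identical(da, d)) return(a)
  out <- array(0, d)
  if (da[3] == 1L && da[1] == d[1] && da[2] == d[2]) {
    for (n in seq_len(d[4])) out[, , , n] <- rep(a[, , 1L, n], d[3])
  } else if (da[1] == 1L && da[2] == 1L && da[3] == d[3]) {
    for (n in seq_len(d[4])) out[, , , n] <- rep(a[1L, 1L, , n], each = d[1] * d[2])
  } else {
    stop("unsupported broadcast from [", paste(da, collapse = ","),
         "] to [", paste(d, collapse = ","), "]")
  }
  out
}

## Sum `g` (dims dg) down to dims d (inverse of bcastTo).
reduceTo <- function(g, d) {
  dg <- dim(g)
  if (identical(dg, d)) return(g)
  out <- array(0, d)
  if (d[3] == 1L) {
    for (n in seq_len(dg[4]))
      out[, , 1L, n] <- rowSums(matrix(g[, , , n], dg[1] * dg[2], dg[3]))
  } else {
    for (n in seq_len(dg[4]))
      out[1L, 1L, , n] <- colSums(matrix(g[, , , n], dg[1] * dg[2], dg[3]))
  }
  out
}

## ---- primitive ops ----------------------------------------------------

## 2-D convolution, stride 1, same padding, square odd kernel; w is an
## agTensor [kh,kw,IC,OC], b an agTensor of length OC.
agConv2d <- function(x, w, b, dil = 1L) {
  v <- cpp_conv2d(x$v, w$v, b$v, as.integer(dil))
  xv <- x$v; wv <- w$v
  agNode(v, list(x, w, b), function(g) {
    r <- cpp_conv2d_backward(xv, wv, g, as.integer(dil))
    list(r$gx, r$gw, r$gb)
  })
}

agMaxPool2 <- function(x) {
  r <- cpp_maxpool2(x$v)
  dx <- dim(x$v)
  agNode(r$y, list(x), function(g) list(cpp_maxpool2_backward(g, r$idx, dx)))
}

agUpsample <- function(x, ho, wo) {
  d <- dim(x$v)
  if (d[1] == ho && d[2] == wo) return(agNode(x$v, list(x), function(g) list(g)))
  v <- cpp_resize_bilinear(x$v, as.integer(ho), as.integer(wo))
  agNode(v, list(x), function(g)
    list(cpp_resize_bilinear_backward(g, d[1], d[2])))
}

agRelu <- function(x) {
  m <- x$v > 0
  agNode(pmax(x$v, 0), list(x), function(g) list(g * m))
}

agSigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  agNode(s, list(x), function(g) list(g * s * (1 - s)))
}

agAdd <- function(x, y) {
  agNode(x$v + y$v, list(x, y), function(g) list(g, g))
}

## Elementwise product with broadcasting of `a` over channels or pixels.
agMulB <- function(x, a) {
  d <- dim(x$v)
  ab <- bcastTo(a$v, d)
  xv <- x$v
  da <- dim(a$v)
  agNode(xv * ab, list(x, a), function(g)
    list(g * ab, reduceTo(g * xv, da)))
}

## Concatenate along the channel axis.
agConcatC <- function(xs) {
  ds <- lapply(xs, function(x) dim(x$v))
  cs <- vapply(ds, `[`, integer(1), 3L)
  d <- ds[[1]]
  v <- array(0, c(d[1], d[2], sum(cs), d[4]))
  off <- 0L
  for (i in seq_along(xs)) {
    v[, , off + seq_len(cs[i]), ] <- xs[[i]]$v
    off <- off + cs[i]
  }
  agNode(v, xs, function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[, , off + seq_len(cs[i]), , drop = FALSE]
      off <- off + cs[i]
    }
    out
  })
}

## Batch normalization over (H, W, N) per channel. gamma/beta are agTensors
## of length C; running stats live in the layer's state environment.
agBatchNorm <- function(x, gamma, beta, state, training, momentum = 0.1,
                        eps = 1e-5) {
  d <- dim(x$v)
  C <- d[3]
  m <- d[1] * d[2] * d[4]
  v <- array(0, d)
  xhat <- array(0, d)
  sdv <- numeric(C)
  for (c in seq_len(C)) {
    xc <- x$v[, , c, , drop = FALSE]
    if (training) {
      mu <- mean(xc)
      va <- mean((xc - mu)^2)
      state$rm[c] <- (1 - momentum) * state$rm[c] + momentum * mu
      state$rv[c] <- (1 - momentum) * state$rv[c] + momentum * va
    } else {
      mu <- state$rm[c]
      va <- state$rv[c]
    }
    sdv[c] <- sqrt(va + eps)
    xh <- (xc - mu) / sdv[c]
    xhat[, , c, ] <- xh
    v[, , c, ] <- gamma$v[c] * xh + beta$v[c]
  }
  agNode(v, list(x, gamma, beta), function(g) {
    gx <- array(0, d)
    gg <- numeric(C)
    gb <- numeric(C)
    for (c in seq_len(C)) {
      gc <- g[, , c, , drop = FALSE]
      xh <- xhat[, , c, , drop = FALSE]
      gg[c] <- sum(gc * xh)
      gb[c] <- sum(gc)
      if (training) {
        gx[, , c, ] <- (gamma$v[c] / sdv[c]) *
          (gc - gb[c] / m - xh * (gg[c] / m))
      } else {
        gx[, , c, ] <- gamma$v[c] / sdv[c] * gc
      }
    }
    list(gx, gg, gb)
  })
}

## Per-pixel mean / max over channels -> [H,W,1,N]
agChannelMean <- function(x) {
  d <- dim(x$v)
  v <- array(0, c(d[1], d[2], 1L, d[4]))
  for (n in seq_len(d[4]))
    v[, , 1L, n] <- rowMeans(matrix(x$v[, , , n], d[1] * d[2], d[3]))
  agNode(v, list(x), function(g) list(bcastTo(g, d) / d[3]))
}

agChannelMax <- function(x) {
  d <- dim(x$v)
  v <- array(0, c(d[1], d[2], 1L, d[4]))
  for (n in seq_len(d[4]))
    v[, , 1L, n] <- do.call(pmax, lapply(seq_len(d[3]), function(c) x$v[, , c, n]))
  xv <- x$v
  agNode(v, list(x), function(g) {
    vb <- bcastTo(v, d)
    m <- (xv == vb) * 1
    cnt <- reduceTo(m, dim(v)) # ties share the gradient
    list(m * bcastTo(g / cnt, d))
  })
}

## Global spatial mean / max -> [1,1,C,N]
agGlobalMean <- function(x) {
  d <- dim(x$v)
  v <- array(0, c(1L, 1L, d[3], d[4]))
  for (n in seq_len(d[4]))
    v[1L, 1L, , n] <- colMeans(matrix(x$v[, , , n], d[1] * d[2], d[3]))
  agNode(v, list(x), function(g) list(bcastTo(g, d) / (d[1] * d[2])))
}

agGlobalMax <- function(x) {
  d <- dim(x$v)
  v <- array(0, c(1L, 1L, d[3], d[4]))
  for (n in seq_len(d[4]))
    v[1L, 1L, , n] <- apply(matrix(x$v[, , , n], d[1] * d[2], d[3]), 2, max)
  xv <- x$v
  agNode(v, list(x), function(g) {
    vb <- bcastTo(v, d)
    m <- (xv == vb) * 1
    cnt <- reduceTo(m, dim(v))
    list(m * bcastTo(g / cnt, d))
  })
}

## Sum of all elements -> scalar tensor.
agSumAll <- function(x) {
  d <- dim(x$v)
  agNode(sum(x$v), list(x), function(g) list(array(g, d)))
}

## Sum a list of scalar tensors.
agSumScalars <- function(xs) {
  v <- sum(vapply(xs, function(x) x$v, numeric(1)))
  agNode(v, xs, function(g) rep(list(g), length(xs)))
}

## Soft Dice loss 1 - (2*sum(y*p)+eps)/(sum(y)+sum(p)+eps); `y` is a plain
## array of the same shape as p$v.
agDiceLoss <- function(p, y, eps = 1e-6) {
  sy <- sum(y)
  sp <- sum(p$v)
  syp <- sum(y * p$v)
  den <- sy + sp + eps
  v <- 1 - (2 * syp + eps) / den
  agNode(v, list(p), function(g)
    list(g * (-(2 * y * den - (2 * syp + eps)) / den^2)))
}

## Binary cross-entropy with probability clipping.
agBCELoss <- function(p, y, delta = 1e-7) {
  n <- length(y)
  pc <- pmin(pmax(p$v, delta), 1 - delta)
  inb <- (p$v > delta) & (p$v < 1 - delta)
  v <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  agNode(v, list(p), function(g)
    list(g * inb * (-(y / pc) + (1 - y) / (1 - pc)) / n))
}
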