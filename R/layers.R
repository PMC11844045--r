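## Parameterized layers. Each constructor returns a classed list of agTensor
## parameters (plus any running state); forward functions take and return
## tensors. Weight initialization is a truncated-normal He scheme: draws are
## clamped at two standard deviations so no single tap dominates early
## training.

truncNormal <- function(n, sd) {
  z <- stats::rnorm(n)
  pmin(pmax(z, -2), 2) * sd
}

initKernel <- function(kh, kw, ic, oc) {
  sd <- sqrt(2 / (kh * kw * ic))
  array(truncNormal(kh * kw * ic * oc, sd), c(kh, kw, ic, oc))
}

newConv <- function(k, ic, oc, dil = 1L) {
  structure(list(w = agTensor(initKernel(k, k, ic, oc), requires = TRUE),
                 b = agTensor(numeric(oc), requires = TRUE),
                 dil = as.integer(dil)),
            class = c("dnConv", "dnModule"))
}

fwdConv <- function(m, x) agConv2d(x, m$w, m$b, m$dil)

newBN <- function(c) {
  st <- new.env(parent = emptyenv())
  st$rm <- numeric(c)
  st$rv <- rep(1, c)
  structure(list(gamma = agTensor(rep(1, c), requires = TRUE),
                 beta = agTensor(numeric(c), requires = TRUE),
                 state = st),
            class = c("dnBN", "dnModule"))
}

fwdBN <- function(m, x, training) agBatchNorm(x, m$gamma, m$beta, m$state, training)

## Conv2d(3x3, same padding = dilation) + BN + ReLU — the basic unit of
## every residual U-block.
newConvUnit <- function(ic, oc, dil = 1L) {
  structure(list(conv = newConv(3L, ic, oc, dil), bn = newBN(oc)),
            class = c("dnConvUnit", "dnModule"))
}

fwdConvUnit <- function(m, x, training = FALSE)
  agRelu(fwdBN(m$bn, fwdConv(m$conv, x), training))

## ---- attention primitives ---------------------------------------------

## Attention gate on a skip connection: both inputs are projected by 1x1
## convolutions to `fint` channels, summed (the gating signal is bilinearly
## upsampled to the skip's resolution first when it comes from a coarser
## level), passed through ReLU, a 1x1 convolution to one channel, and a
## sigmoid; the resulting coefficient map scales the skip feature.
newAttnGate <- function(cx, cg, fint = NULL) {
  if (is.null(fint)) fint <- max(1L, cx %/% 2L)
  structure(list(wx = newConv(1L, cx, fint),
                 wg = newConv(1L, cg, fint),
                 psi = newConv(1L, fint, 1L),
                 fint = as.integer(fint)),
            class = c("dnAttnGate", "dnModule"))
}

fwdAttnGate <- function(m, x, g, return_alpha = FALSE) {
  dx <- dim(x$v)
  dg <- dim(g$v)
  if (dx[4] != dg[4]) stop("batch mismatch")
  same <- dx[1] == dg[1] && dx[2] == dg[2]
  half <- dg[1] * 2L == dx[1] && dg[2] * 2L == dx[2]
  if (!same && !half) stop("incompatible gate resolution")
  px <- fwdConv(m$wx, x)
  pg <- fwdConv(m$wg, g)
  if (!same) pg <- agUpsample(pg, dx[1], dx[2])
  alpha <- agSigmoid(fwdConv(m$psi, agRelu(agAdd(px, pg))))
  out <- agMulB(x, alpha)
  if (return_alpha) list(out = out, alpha = alpha) else out
}

## Spatial attention (SAM): per-pixel mean and max over channels, stacked,
## one kxk convolution (k = 7 by default) to a single channel, sigmoid,
## broadcast over channels.
newSAM <- function(k = 7L) {
  if (k %% 2L == 0L) stop("kernel must be odd")
  structure(list(conv = newConv(as.integer(k), 2L, 1L)),
            class = c("dnSAM", "dnModule"))
}

fwdSAM <- function(m, x, return_alpha = FALSE) {
  s <- agConcatC(list(agChannelMean(x), agChannelMax(x)))
  alpha <- agSigmoid(fwdConv(m$conv, s))
  out <- agMulB(x, alpha)
  if (return_alpha) list(out = out, alpha = alpha) else out
}

## Channel attention (CAM): global mean and max pooling to C-vectors, a
## shared two-layer bottleneck transform (C -> C/r -> C with ReLU between),
## branch outputs summed, sigmoid, broadcast over pixels.
newCAM <- function(c, reduction = 16L) {
  if (reduction < 1L) stop("reduction must be >= 1")
  cr <- max(1L, c %/% as.integer(reduction))
  structure(list(fc1 = newConv(1L, c, cr), fc2 = newConv(1L, cr, c)),
            class = c("dnCAM", "dnModule"))
}

fwdCAM <- function(m, x, return_alpha = FALSE) {
  branch <- function(p) fwdConv(m$fc2, agRelu(fwdConv(m$fc1, p)))
  pre <- agAdd(branch(agGlobalMean(x)), branch(agGlobalMax(x)))
  alpha <- agSigmoid(pre)
  out <- agMulB(x, alpha)
  if (return_alpha) list(out = out, alpha = alpha) else out
}

## ---- module tree utilities --------------------------------------------

## Walk a (nested list) module and collect all trainable agTensors, named by
## their path, e.g. "en1.enc.2.conv.w".
collectParams <- function(m, prefix = "") {
  if (is.agTensor(m)) {
    if (isTRUE(m$requires)) {
      out <- list(m)
      names(out) <- prefix
      return(out)
    }
    return(list())
  }
  if (is.list(m)) {
    nm <- names(m)
    out <- list()
    for (i in seq_along(m)) {
      tag <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      key <- if (nzchar(prefix)) paste(prefix, tag, sep = ".") else tag
      out <- c(out, collectParams(m[[i]], key))
    }
    return(out)
  }
  list()
}

## Count sub-modules of a given class (e.g. "dnAttnGate").
countModules <- function(m, cls) {
  if (!is.list(m)) return(0L)
  n <- if (inherits(m, cls)) 1L else 0L
  for (el in m) if (is.list(el)) n <- n + countModules(el, cls)
  n
}

## Snapshot / restore all state (parameters + BN running moments) of a
## module tree, named by path. Used by the checkpoint round-trip.
moduleState <- function(m, prefix = "") {
  out <- collectParams(m, prefix)
  out <- lapply(out, function(p) p$v)
  grab <- function(m, prefix) {
    res <- list()
    if (inherits(m, "dnBN")) {
      res[[paste0(prefix, ".state.rm")]] <- m$state$rm
      res[[paste0(prefix, ".state.rv")]] <- m$state$rv
    }
    if (is.list(m)) {
      nm <- names(m)
      for (i in seq_along(m)) {
        if (!is.list(m[[i]])) next
        tag <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
        key <- if (nzchar(prefix)) paste(prefix, tag, sep = ".") else tag
        res <- c(res, grab(m[[i]], key))
      }
    }
    res
  }
  c(out, grab(m, prefix))
}

loadModuleState <- function(m, state, prefix = "") {
  params <- collectParams(m, prefix)
  for (nm in names(params)) {
    if (is.null(state[[nm]])) stop("checkpoint is missing parameter ", nm)
    params[[nm]]$v <- state[[nm]]
    params[[nm]]$grad <- NULL
  }
  put <- function(m, prefix) {
    if (inherits(m, "dnBN")) {
      m$state$rm <- state[[paste0(prefix, ".state.rm")]]
      m$state$rv <- state[[paste0(prefix, ".state.rv")]]
    }
    if (is.list(m)) {
      nm <- names(m)
      for (i in seq_along(m)) {
        if (!is.list(m[[i]])) next
        tag <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
        key <- if (nzchar(prefix)) paste(prefix, tag, sep = ".") else tag
        put(m[[i]], key)
      }
    }
  }
  put(m, prefix)
  invisible(m)
}
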