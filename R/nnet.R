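#' @include AllGenerics.R
NULL

## Compact 3D convolutional network engine. Feature maps are (nvox, C)
## matrices with column-major voxel order; convolutions are 3x3x3 with zero
## padding 1, realized as im2col + GEMM so the heavy lifting stays in BLAS.
## Backpropagation is hand-written per architecture (U-Net generator,
## strided-conv discriminator, residual downsampler) and optimized with Adam.
## Processing is per-sample; batches are accumulated by the training loop.

convInit <- function(cin, cout, zero = FALSE, scale = 1) {
  fan <- 27 * cin
  W <- if (zero) matrix(0, fan, cout)
       else matrix(rnorm(fan * cout, sd = scale * sqrt(2 / fan)), fan, cout)
  list(W = W, b = numeric(cout))
}

# convolutions default to single precision (the networks train on noisy
# stochastic gradients and the step is memory-bound); set
# options(dmrisynth.convSingle = FALSE) for exact double-precision passes
convSingle <- function() {
  isTRUE(getOption("dmrisynth.convSingle", TRUE))
}

convF <- function(x, dims, p, stride = 1L, keepCache = FALSE, B = 1L) {
  y <- cpp_conv3_fwd(x, as.integer(dims), p$W, p$b, stride, convSingle(), B)
  list(y = y, x = x, dims = dims, stride = stride, B = B)
}

# the im2col matrix is rebuilt sample-by-sample in compiled code (it stays
# cache-resident that way) rather than cached between passes
convB <- function(dy, cc, p, needDx = TRUE) {
  r <- cpp_conv3_bwd(cc$x, as.integer(cc$dims), p$W, dy, cc$stride, needDx,
                     convSingle(), cc$B)
  list(dx = if (needDx) r$dx else NULL,
       g = list(W = r$dW, b = as.numeric(r$db)))
}

actF <- function(name, x, bound = 1) {
  switch(name,
    relu = (x > 0) * x,
    lrelu = {p <- x > 0; p * x + 0.2 * (!p) * x},
    sigmoid = 1 / (1 + exp(-x)),
    tanh = tanh(x),
    hardtanh = pmin(pmax(x, -bound), bound),
    linear = x,
    stop("unknown activation: ", name))
}

actB <- function(name, x, y, dy, bound = 1) {
  switch(name,
    relu = dy * (x > 0),
    lrelu = {p <- x > 0; dy * (p + 0.2 * !p)},
    sigmoid = dy * y * (1 - y),
    tanh = dy * (1 - y^2),
    hardtanh = dy * (x > -bound & x < bound),
    linear = dy)
}

newNet <- function(kind, spec, par) {
  net <- new.env(parent = emptyenv())
  net$kind <- kind
  net$spec <- spec
  net$par <- par
  net$grad <- NULL
  net$adam <- NULL
  class(net) <- "dmrisynthNet"
  net
}

#' @export
print.dmrisynthNet <- function(x, ...) {
  cat(sprintf("<%s network: %d parameters>\n", x$kind, nParams(x)))
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param net a network built by [buildGenerator()], [buildDiscriminator()] or
#'   [buildDownsampler()].
#' @return Integer parameter count.
#' @export
nParams <- function(net) {
  sum(vapply(net$par, function(p) length(p$W) + length(p$b), numeric(1)))
}

zeroGrad <- function(net) {
  net$grad <- lapply(net$par, function(p)
    list(W = matrix(0, nrow(p$W), ncol(p$W)), b = numeric(length(p$b))))
  invisible(net)
}

addGrad <- function(net, name, g) {
  net$grad[[name]]$W <- net$grad[[name]]$W + g$W
  net$grad[[name]]$b <- net$grad[[name]]$b + g$b
  invisible(net)
}

scaleGrad <- function(net, f) {
  net$grad <- lapply(net$grad, function(g) list(W = g$W * f, b = g$b * f))
  invisible(net)
}

adamInit <- function(net) {
  net$adam <- list(t = 0, m = lapply(net$par, function(p)
    list(W = matrix(0, nrow(p$W), ncol(p$W)), b = numeric(length(p$b)))),
    v = lapply(net$par, function(p)
      list(W = matrix(0, nrow(p$W), ncol(p$W)), b = numeric(length(p$b)))))
  invisible(net)
}

adamStep <- function(net, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  if (is.null(net$adam)) adamInit(net)
  a <- net$adam
  a$t <- a$t + 1
  bc1 <- 1 - beta1^a$t
  bc2 <- 1 - beta2^a$t
  for (nm in names(net$par)) {
    for (fld in c("W", "b")) {
      g <- net$grad[[nm]][[fld]]
      a$m[[nm]][[fld]] <- beta1 * a$m[[nm]][[fld]] + (1 - beta1) * g
      a$v[[nm]][[fld]] <- beta2 * a$v[[nm]][[fld]] + (1 - beta2) * g^2
      mh <- a$m[[nm]][[fld]] / bc1
      vh <- a$v[[nm]][[fld]] / bc2
      net$par[[nm]][[fld]] <- net$par[[nm]][[fld]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  net$adam <- a
  invisible(net)
}

## ---- instance normalization ------------------------------------------------
## per-sample, per-channel standardization with learned scale/shift; the
## scale lives in $W (1 x C) and the shift in $b so the Adam updater can
## treat it like any other parameter pair

inInit <- function(channels) {
  list(W = matrix(1, 1, channels), b = numeric(channels))
}

inForward <- function(x, p, B = 1L, eps = 1e-5) {
  r <- cpp_in_fwd(x, as.numeric(p$W), p$b, eps, B)
  r$B <- B
  r
}

inBackward <- function(dy, cc, p) {
  r <- cpp_in_bwd(dy, cc$xhat, cc$invsd, as.numeric(p$W), cc$B)
  list(dx = r$dx, g = list(W = matrix(as.numeric(r$dg), 1),
                           b = as.numeric(r$db)))
}

## ---- U-Net generator -------------------------------------------------------

unetWidths <- function(spec) spec$baseWidth * 2^(seq_len(spec$depth) - 1)

useIN <- function(spec) isTRUE(spec$instanceNorm)

## Instance normalization is applied in the interior of the U-Net only: the
## outermost encoder and decoder blocks stay un-normalized so absolute input
## intensities (which carry tissue information) can reach the output head.
unetInit <- function(spec) {
  par <- list()
  w <- unetWidths(spec)
  norm <- useIN(spec)
  cin <- spec$inChannels
  for (l in seq_len(spec$depth)) {
    for (k in seq_len(spec$convsPerBlock)) {
      par[[sprintf("enc%d.c%d", l, k)]] <- convInit(if (k == 1) cin else w[l], w[l])
      if (norm) par[[sprintf("enc%d.n%d", l, k)]] <- inInit(w[l])
    }
    cin <- w[l]
  }
  wb <- spec$baseWidth * 2^spec$depth
  for (k in seq_len(spec$convsPerBlock)) {
    par[[sprintf("bott.c%d", k)]] <- convInit(if (k == 1) cin else wb, wb)
    if (norm) par[[sprintf("bott.n%d", k)]] <- inInit(wb)
  }
  lower <- wb
  for (l in rev(seq_len(spec$depth))) {
    par[[sprintf("up%d", l)]] <- convInit(lower, w[l])
    if (norm) par[[sprintf("up%dn", l)]] <- inInit(w[l])
    for (k in seq_len(spec$convsPerBlock)) {
      par[[sprintf("dec%d.c%d", l, k)]] <- convInit(if (k == 1) 2 * w[l] else w[l], w[l])
      if (norm) par[[sprintf("dec%d.n%d", l, k)]] <- inInit(w[l])
    }
    lower <- w[l]
  }
  # the output head starts small: untrained generators then synthesize the
  # manifold base point (near-isotropic tensors / near-uniform ODFs) instead
  # of arbitrary anisotropy, and adversarial training starts gently
  par[["final"]] <- convInit(w[1], spec$outChannels, scale = 0.05)
  par
}

# one conv (+ optional instance norm) + ReLU stage; nmN = "" disables norm
unetStageF <- function(net, cur, curDims, nmC, nmN, keep, cc, B = 1L) {
  cf <- convF(cur, curDims, net$par[[nmC]], keepCache = keep, B = B)
  if (nzchar(nmN) && !is.null(net$par[[nmN]])) {
    nf <- inForward(cf$y, net$par[[nmN]], B)
    y <- actF("relu", nf$y)
    if (keep) cc[[nmC]] <- list(conv = cf, normed = nf, pre = nf$y)
  } else {
    y <- actF("relu", cf$y)
    if (keep) cc[[nmC]] <- list(conv = cf, pre = cf$y)
  }
  list(y = y, cc = cc)
}

unetForward <- function(net, x, dims, keep = FALSE, B = 1L) {
  spec <- net$spec
  cc <- if (keep) list() else NULL
  cur <- x
  curDims <- dims
  skips <- vector("list", spec$depth)
  for (l in seq_len(spec$depth)) {
    for (k in seq_len(spec$convsPerBlock)) {
      st <- unetStageF(net, cur, curDims, sprintf("enc%d.c%d", l, k),
                       sprintf("enc%d.n%d", l, k), keep, cc, B)
      cur <- st$y
      cc <- st$cc
    }
    skips[[l]] <- list(x = cur, dims = curDims)
    cur <- cpp_avgpool2(cur, as.integer(curDims), B)
    curDims <- curDims / 2
  }
  for (k in seq_len(spec$convsPerBlock)) {
    st <- unetStageF(net, cur, curDims, sprintf("bott.c%d", k),
                     sprintf("bott.n%d", k), keep, cc, B)
    cur <- st$y
    cc <- st$cc
  }
  for (l in rev(seq_len(spec$depth))) {
    cur <- cpp_upsample2(cur, as.integer(curDims), B)
    curDims <- curDims * 2
    st <- unetStageF(net, cur, curDims, sprintf("up%d", l),
                     sprintf("up%dn", l), keep, cc, B)
    cur <- st$y
    cc <- st$cc
    cur <- cbind(skips[[l]]$x, cur)
    for (k in seq_len(spec$convsPerBlock)) {
      st <- unetStageF(net, cur, curDims, sprintf("dec%d.c%d", l, k),
                       sprintf("dec%d.n%d", l, k), keep, cc, B)
      cur <- st$y
      cc <- st$cc
    }
  }
  cf <- convF(cur, curDims, net$par[["final"]], keepCache = keep, B = B)
  out <- actF(spec$finalActivation, cf$y, spec$activationBound)
  if (keep) cc[["final"]] <- list(conv = cf, pre = cf$y, post = out)
  list(y = out, dims = curDims, cache = cc)
}

# backward through one stage; returns gradient w.r.t. the conv input
unetStageB <- function(net, cc, d, nmC, nmN, accumulate, needDx = TRUE) {
  e <- cc[[nmC]]
  d <- actB("relu", e$pre, NULL, d)
  if (!is.null(e$normed)) {
    nb <- inBackward(d, e$normed, net$par[[nmN]])
    if (accumulate) addGrad(net, nmN, nb$g)
    d <- nb$dx
  }
  cb <- convB(d, e$conv, net$par[[nmC]], needDx = needDx)
  if (accumulate) addGrad(net, nmC, cb$g)
  cb$dx
}

unetBackward <- function(net, cache, dy, accumulate = TRUE, needDx = TRUE) {
  spec <- net$spec
  w <- unetWidths(spec)
  cc <- cache
  fin <- cc[["final"]]
  d <- actB(spec$finalActivation, fin$pre, fin$post, dy, spec$activationBound)
  cb <- convB(d, fin$conv, net$par[["final"]])
  if (accumulate) addGrad(net, "final", cb$g)
  d <- cb$dx
  dskips <- vector("list", spec$depth)
  for (l in seq_len(spec$depth)) {
    for (k in rev(seq_len(spec$convsPerBlock)))
      d <- unetStageB(net, cc, d, sprintf("dec%d.c%d", l, k),
                      sprintf("dec%d.n%d", l, k), accumulate)
    # split the concat: first w[l] columns went to the skip, rest to the up path
    dskips[[l]] <- d[, seq_len(w[l]), drop = FALSE]
    d <- d[, w[l] + seq_len(ncol(d) - w[l]), drop = FALSE]
    d <- unetStageB(net, cc, d, sprintf("up%d", l), sprintf("up%dn", l),
                    accumulate)
    d <- cpp_upsample2_adj(d, as.integer(cc[[sprintf("up%d", l)]]$conv$dims / 2),
                           cc[[sprintf("up%d", l)]]$conv$B)
  }
  for (k in rev(seq_len(spec$convsPerBlock)))
    d <- unetStageB(net, cc, d, sprintf("bott.c%d", k), sprintf("bott.n%d", k),
                    accumulate)
  for (l in rev(seq_len(spec$depth))) {
    d <- cpp_avgpool2_adj(d, as.integer(cc[[sprintf("enc%d.c1", l)]]$conv$dims),
                          cc[[sprintf("enc%d.c1", l)]]$conv$B)
    d <- d + dskips[[l]]
    for (k in rev(seq_len(spec$convsPerBlock))) {
      last <- l == 1 && k == 1
      d <- unetStageB(net, cc, d, sprintf("enc%d.c%d", l, k),
                      sprintf("enc%d.n%d", l, k), accumulate,
                      needDx = needDx || !last)
    }
  }
  d
}

## ---- Discriminator ---------------------------------------------------------

discInit <- function(spec) {
  par <- list()
  cin <- spec$inChannels
  for (i in seq_along(spec$widths)) {
    w <- spec$widths[i]
    par[[sprintf("d%d.a", i)]] <- convInit(cin, w)
    par[[sprintf("d%d.b", i)]] <- convInit(w, w)
    cin <- w
  }
  par[["score"]] <- convInit(cin, 1)
  par
}

discForward <- function(net, x, dims, keep = FALSE, B = 1L) {
  cc <- if (keep) list() else NULL
  cur <- x
  curDims <- dims
  for (i in seq_along(net$spec$widths)) {
    for (s in c("a", "b")) {
      nm <- sprintf("d%d.%s", i, s)
      stride <- if (s == "b") 2L else 1L
      cf <- convF(cur, curDims, net$par[[nm]], stride, keepCache = keep, B = B)
      y <- actF("lrelu", cf$y)
      if (keep) cc[[nm]] <- list(conv = cf, pre = cf$y)
      cur <- y
      if (stride == 2L) curDims <- ceiling(curDims / 2)
    }
  }
  cf <- convF(cur, curDims, net$par[["score"]], keepCache = keep, B = B)
  # one score per sample: mean over each sample's voxels
  n1 <- nrow(cf$y) %/% B
  score <- as.numeric(rowsum(as.numeric(cf$y), rep(seq_len(B), each = n1))) / n1
  if (B == 1L) score <- score[1]
  if (keep) cc[["score"]] <- list(conv = cf, n = n1, B = B)
  list(y = score, cache = cc)
}

discBackward <- function(net, cache, dscore, accumulate = TRUE, needDx = TRUE) {
  e <- cache[["score"]]
  d <- matrix(rep(dscore / e$n, each = e$n), ncol = 1)
  cb <- convB(d, e$conv, net$par[["score"]])
  if (accumulate) addGrad(net, "score", cb$g)
  d <- cb$dx
  for (i in rev(seq_along(net$spec$widths))) {
    for (s in c("b", "a")) {
      nm <- sprintf("d%d.%s", i, s)
      e <- cache[[nm]]
      d <- actB("lrelu", e$pre, NULL, d)
      last <- i == 1 && s == "a"
      cb <- convB(d, e$conv, net$par[[nm]], needDx = needDx || !last)
      if (accumulate) addGrad(net, nm, cb$g)
      d <- cb$dx
    }
  }
  d
}

## ---- Residual downsampler F ------------------------------------------------

downInit <- function(spec) {
  h <- spec$hidden
  C <- spec$channels
  list(
    r1 = convInit(C, h),
    r2 = convInit(h, h),
    r3 = convInit(h, C, zero = TRUE)  # start as pure trilinear resampling
  )
}

downForward <- function(net, x, dims, keep = FALSE, B = 1L) {
  spec <- net$spec
  r <- cpp_resample3(x, as.integer(dims), spec$hrSpacing,
                     as.integer(spec$lrDim), spec$lrSpacing, B)
  c1 <- convF(r, spec$lrDim, net$par$r1, keepCache = keep, B = B)
  a1 <- actF("relu", c1$y)
  c2 <- convF(a1, spec$lrDim, net$par$r2, keepCache = keep, B = B)
  a2 <- actF("relu", c2$y)
  c3 <- convF(a2, spec$lrDim, net$par$r3, keepCache = keep, B = B)
  out <- r + c3$y
  cc <- NULL
  if (keep) cc <- list(c1 = c1, c2 = c2, c3 = c3, srcDims = dims, B = B)
  list(y = out, dims = spec$lrDim, cache = cc)
}

downBackward <- function(net, cache, dy, accumulate = TRUE, needDx = TRUE) {
  spec <- net$spec
  cb3 <- convB(dy, cache$c3, net$par$r3)
  if (accumulate) addGrad(net, "r3", cb3$g)
  d <- actB("relu", cache$c2$y, NULL, cb3$dx)
  cb2 <- convB(d, cache$c2, net$par$r2)
  if (accumulate) addGrad(net, "r2", cb2$g)
  d <- actB("relu", cache$c1$y, NULL, cb2$dx)
  cb1 <- convB(d, cache$c1, net$par$r1)
  if (accumulate) addGrad(net, "r1", cb1$g)
  dr <- dy + cb1$dx  # gradient w.r.t. the resampled field (identity + residual)
  if (!needDx) return(NULL)
  cpp_resample3_adj(dr, as.integer(cache$srcDims), spec$hrSpacing,
                    as.integer(spec$lrDim), spec$lrSpacing, cache$B)
}

## ---- dispatch --------------------------------------------------------------

netForward <- function(net, x, dims, keep = FALSE, B = 1L) {
  switch(net$kind,
    unet = unetForward(net, x, dims, keep, B),
    disc = discForward(net, x, dims, keep, B),
    resdown = downForward(net, x, dims, keep, B))
}

netBackward <- function(net, cache, dy, accumulate = TRUE, needDx = TRUE) {
  switch(net$kind,
    unet = unetBackward(net, cache, dy, accumulate, needDx),
    disc = discBackward(net, cache, dy, accumulate, needDx),
    resdown = downBackward(net, cache, dy, accumulate, needDx))
}
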