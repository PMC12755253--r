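# MambaFormer network: parameter tree, batched forward pass and hand-derived
# backward pass.
#
# Pipeline (grid-preserving; the LR input is expected pre-resampled to the
# HR grid):
#   x -> 3x3 conv embed (1 -> D) -> stages of MambaFormer blocks
#     -> 3x3 body conv -> + embed features (global feature residual)
#     -> 3x3 conv (D -> 1) -> + x (global image residual)
# Each block (pre-norm, two residual sub-layers):
#   z'  = z  + MHSSM(LN(z))
#   z'' = z' + ChannelMLP(LN(z'))

.nBlocks <- function(cfg) sum(cfg@stageRepeats)

.initHeadParams <- function(D, N, hd, selective) {
  h <- list(aRaw = log(seq_len(N)), Dskip = rep(1, D),
            dW1 = matrix(rnorm(hd * D, sd = 0.02), hd, D), db1 = rep(0, hd),
            dW2 = matrix(rnorm(hd, sd = 0.02), 1L, hd),
            db2 = log(expm1(0.05)))
  if (selective) {
    h$WB <- matrix(rnorm(N * D, sd = 1 / sqrt(D)), N, D)
    h$WC <- matrix(rnorm(N * D, sd = 1 / sqrt(D)), N, D)
  } else {
    h$B <- rep(1, N)
    h$C <- rep(0, N)
  }
  h
}

.initBlockParams <- function(cfg) {
  D <- cfg@embedDim
  m <- cfg@heads
  N <- cfg@stateSize
  hd <- max(2L, D %/% 8L)
  aD <- as.integer(round(cfg@alpha * D))
  w <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
  attn <- list(
    inp = list(W = w(D, D), b = rep(0, D)),
    dw = list(K = w(D, 9L), b = rep(0, D)),
    heads = lapply(seq_len(m), function(j)
      .initHeadParams(D, N, hd, cfg@selectiveBC)),
    lnm = list(g = rep(1, m * D), b = rep(0, m * D)),
    out = list(W = matrix(0, D, m * D), b = rep(0, D))
  )
  if (cfg@gated) attn$gate <- list(W = w(D, D), b = rep(0, D))
  list(
    ln1 = list(g = rep(1, D), b = rep(0, D)),
    attn = attn,
    ln2 = list(g = rep(1, D), b = rep(0, D)),
    mlp = list(inp = list(W = w(aD, D), b = rep(0, aD)),
               out = list(W = matrix(0, D, aD %/% 2L), b = rep(0, D)))
  )
}

.initParams <- function(cfg) {
  D <- cfg@embedDim
  set.seed(cfg@seed)
  list(
    embed = list(W = matrix(rnorm(D * 9L, sd = 0.02), D, 9L), b = rep(0, D)),
    blocks = lapply(seq_len(.nBlocks(cfg)), function(i) .initBlockParams(cfg)),
    body = list(W = matrix(rnorm(D * 9L * D, sd = 0.02), D, 9L * D),
                b = rep(0, D)),
    tail = list(W = matrix(0, 1L, 9L * D), b = 0)
  )
}

# Residual-branch output layers (block output projections, body conv, tail
# conv) set to zero: the network becomes the identity map on images.
.zeroResidual <- function(params) {
  for (i in seq_along(params$blocks)) {
    params$blocks[[i]]$attn$out$W[] <- 0
    params$blocks[[i]]$attn$out$b[] <- 0
    params$blocks[[i]]$mlp$out$W[] <- 0
    params$blocks[[i]]$mlp$out$b[] <- 0
  }
  params$body$W[] <- 0
  params$body$b[] <- 0
  params$tail$W[] <- 0
  params$tail$b[] <- 0
  params
}

# Per-(H, W, batch) geometry: shift indices and batched serialization
# columns for every scan order.
.modelContext <- function(cfg, H, W, batch, scanSet = NULL) {
  ss <- if (is.null(scanSet)) buildScanSet(H, W, cfg@scanType, cfg@scanCount)
        else scanSet
  P <- H * W
  sidx <- lapply(ss@orders, function(o)
    as.integer(outer(o@order + 1L, (0:(batch - 1L)) * as.integer(P), `+`)))
  list(sh = .shiftIndices(H, W, batch), scanSet = ss, sidx = sidx,
       H = H, W = W, batch = batch, P = P)
}

.imagesToBatch <- function(imgs) {
  if (is.matrix(imgs)) imgs <- list(imgs)
  do.call(cbind, lapply(imgs, function(im) matrix(as.vector(t(im)), nrow = 1L)))
}

.batchToImages <- function(Y, H, W, batch) {
  lapply(seq_len(batch), function(b)
    matrix(Y[1L, (b - 1L) * H * W + seq_len(H * W)], H, W, byrow = TRUE))
}

# ---- MHSSM sub-layer -------------------------------------------------------

.attnForward <- function(Tn, w, cfg, ctx, train) {
  m <- cfg@heads
  D <- cfg@embedDim
  Tt <- ncol(Tn)
  cU <- .pwForward(Tn, w$inp$W, w$inp$b)
  gated <- cfg@gated
  if (gated) {
    cG <- .pwForward(Tn, w$gate$W, w$gate$b)
    Gs <- silu(cG$y)
  }
  cV <- .dwConvForward(cU$y, w$dw$K, w$dw$b, ctx$sh)
  Va <- silu(cV$y)
  Ycat <- matrix(0, m * D, Tt)
  headCaches <- vector("list", m)
  for (j in seq_len(m)) {
    hw <- w$heads[[j]]
    # B/C/delta projections are columnwise, so they commute with the scan
    # permutation: compute them in grid order and let the kernel traverse
    hidPre <- hw$dW1 %*% Va + hw$db1
    hid <- silu(hidPre)
    dpre <- hw$dW2 %*% hid + hw$db2
    delta <- as.vector(softplus(dpre))
    if (cfg@selectiveBC) {
      Bsel <- hw$WB %*% Va
      Csel <- hw$WC %*% Va
    } else {
      Bsel <- matrix(hw$B, cfg@stateSize, Tt)
      Csel <- matrix(hw$C, cfg@stateSize, Tt)
    }
    A <- -exp(hw$aRaw)
    sc <- .scanForwardCpp(Va, delta, A, Bsel, Csel, hw$Dskip,
                          ctx$sidx[[j]], ctx$batch, train)
    Ycat[(j - 1L) * D + seq_len(D), ] <- sc$y
    if (train)
      headCaches[[j]] <- list(hidPre = hidPre, hid = hid,
                              dpre = dpre, delta = delta, Bsel = Bsel,
                              Csel = Csel, A = A, scan = sc)
  }
  cLn <- .lnForward(Ycat, w$lnm$g, w$lnm$b)
  Yg <- if (gated) cLn$y * Gs[rep(seq_len(D), m), , drop = FALSE] else cLn$y
  cOut <- .pwForward(Yg, w$out$W, w$out$b)
  cache <- if (train) list(cU = cU, cV = cV, Va = Va, cLn = cLn, Yg = Yg,
                           cOut = cOut, headCaches = headCaches,
                           Gpre = if (gated) cG$y else NULL,
                           Gs = if (gated) Gs else NULL,
                           cGx = if (gated) cG else NULL) else NULL
  list(y = cOut$y, cache = cache)
}

.attnBackward <- function(dY, cache, w, cfg, ctx) {
  m <- cfg@heads
  D <- cfg@embedDim
  gw <- list()
  bOut <- .pwBackward(dY, cache$cOut, w$out$W)
  gw$out <- list(W = bOut$dW, b = bOut$db)
  dYg <- bOut$dX
  if (cfg@gated) {
    GsT <- cache$Gs[rep(seq_len(D), m), , drop = FALSE]
    dLnY <- dYg * GsT
    dGs <- matrix(0, D, ncol(dY))
    for (j in seq_len(m)) {
      rows <- (j - 1L) * D + seq_len(D)
      dGs <- dGs + dYg[rows, , drop = FALSE] * cache$cLn$y[rows, , drop = FALSE]
    }
    dG <- dGs * siluGrad(cache$Gpre)
    bG <- .pwBackward(dG, cache$cGx, w$gate$W)
    gw$gate <- list(W = bG$dW, b = bG$db)
    dTnGate <- bG$dX
  } else {
    dLnY <- dYg
    dTnGate <- 0
  }
  bLn <- .lnBackward(dLnY, cache$cLn, w$lnm$g)
  gw$lnm <- list(g = bLn$dg, b = bLn$db)
  dYcat <- bLn$dX
  dVa <- matrix(0, D, ncol(dY))
  gw$heads <- vector("list", m)
  Va <- cache$Va
  for (j in seq_len(m)) {
    hc <- cache$headCaches[[j]]
    hw <- w$heads[[j]]
    gj <- dYcat[(j - 1L) * D + seq_len(D), , drop = FALSE]
    bs <- .scanBackwardCpp(gj, Va, hc$delta, hc$A, hc$Bsel, hc$Csel,
                           hw$Dskip, hc$scan$h, hc$scan$abar, hc$scan$phi,
                           ctx$sidx[[j]], ctx$batch)
    duj <- bs$du
    hg <- list(aRaw = bs$dA * hc$A, Dskip = bs$dD)
    if (cfg@selectiveBC) {
      hg$WB <- tcrossprod(bs$dB, Va)
      hg$WC <- tcrossprod(bs$dC, Va)
      duj <- duj + crossprod(hw$WB, bs$dB) + crossprod(hw$WC, bs$dC)
    } else {
      hg$B <- rowSums(bs$dB)
      hg$C <- rowSums(bs$dC)
    }
    ddpre <- matrix(bs$ddelta * softplusGrad(as.vector(hc$dpre)), 1L)
    hg$dW2 <- tcrossprod(ddpre, hc$hid)
    hg$db2 <- sum(ddpre)
    dhid <- crossprod(hw$dW2, ddpre) * siluGrad(hc$hidPre)
    hg$dW1 <- tcrossprod(dhid, Va)
    hg$db1 <- rowSums(dhid)
    duj <- duj + crossprod(hw$dW1, dhid)
    # reorder head gradient names to match the parameter tree
    ord <- names(w$heads[[j]])
    gw$heads[[j]] <- hg[ord]
    dVa <- dVa + duj
  }
  dV <- dVa * siluGrad(cache$cV$y)
  bDw <- .dwConvBackward(dV, cache$cV, w$dw$K, ctx$sh)
  gw$dw <- list(K = bDw$dK, b = bDw$db)
  bIn <- .pwBackward(bDw$dX, cache$cU, w$inp$W)
  gw$inp <- list(W = bIn$dW, b = bIn$db)
  ord <- names(w)
  list(dX = bIn$dX + dTnGate, gw = gw[ord])
}

# ---- Channel MLP sub-layer -------------------------------------------------

.mlpForward <- function(Tn, w, train) {
  cIn <- .pwForward(Tn, w$inp$W, w$inp$b)
  aD <- nrow(w$inp$W)
  half <- aD %/% 2L
  x1 <- cIn$y[seq_len(half), , drop = FALSE]
  x2 <- cIn$y[half + seq_len(half), , drop = FALSE]
  Pm <- x1 * x2
  cOut <- .pwForward(Pm, w$out$W, w$out$b)
  list(y = cOut$y,
       cache = if (train) list(cIn = cIn, x1 = x1, x2 = x2, cOut = cOut,
                               half = half) else NULL)
}

.mlpBackward <- function(dY, cache, w) {
  bOut <- .pwBackward(dY, cache$cOut, w$out$W)
  dPm <- bOut$dX
  half <- cache$half
  dH <- matrix(0, 2L * half, ncol(dPm))
  dH[seq_len(half), ] <- dPm * cache$x2
  dH[half + seq_len(half), ] <- dPm * cache$x1
  bIn <- .pwBackward(dH, cache$cIn, w$inp$W)
  list(dX = bIn$dX,
       gw = list(inp = list(W = bIn$dW, b = bIn$db),
                 out = list(W = bOut$dW, b = bOut$db)))
}

# ---- full block ------------------------------------------------------------

.blockForward <- function(Z, w, cfg, ctx, train) {
  cLn1 <- .lnForward(Z, w$ln1$g, w$ln1$b)
  at <- .attnForward(cLn1$y, w$attn, cfg, ctx, train)
  Z1 <- Z + at$y
  cLn2 <- .lnForward(Z1, w$ln2$g, w$ln2$b)
  ml <- .mlpForward(cLn2$y, w$mlp, train)
  list(y = Z1 + ml$y,
       cache = if (train) list(cLn1 = cLn1, at = at$cache, cLn2 = cLn2,
                               ml = ml$cache) else NULL)
}

.blockBackward <- function(dY, cache, w, cfg, ctx) {
  bMl <- .mlpBackward(dY, cache$ml, w$mlp)
  bLn2 <- .lnBackward(bMl$dX, cache$cLn2, w$ln2$g)
  dZ1 <- dY + bLn2$dX
  bAt <- .attnBackward(dZ1, cache$at, w$attn, cfg, ctx)
  bLn1 <- .lnBackward(bAt$dX, cache$cLn1, w$ln1$g)
  list(dX = dZ1 + bLn1$dX,
       gw = list(ln1 = list(g = bLn1$dg, b = bLn1$db),
                 attn = bAt$gw,
                 ln2 = list(g = bLn2$dg, b = bLn2$db),
                 mlp = bMl$gw))
}

# ---- whole model -----------------------------------------------------------

.modelForward <- function(params, cfg, X0, ctx, train = FALSE) {
  cEmbed <- .conv3Forward(X0, params$embed$W, params$embed$b, ctx$sh)
  F0 <- cEmbed$y
  Z <- F0
  blockCaches <- if (train) vector("list", length(params$blocks)) else NULL
  for (i in seq_along(params$blocks)) {
    bf <- .blockForward(Z, params$blocks[[i]], cfg, ctx, train)
    Z <- bf$y
    if (train) blockCaches[[i]] <- bf$cache
  }
  cBody <- .conv3Forward(Z, params$body$W, params$body$b, ctx$sh)
  Ff <- F0 + cBody$y
  cTail <- .conv3Forward(Ff, params$tail$W, params$tail$b, ctx$sh)
  Y <- cTail$y + X0
  list(y = Y,
       cache = if (train) list(cEmbed = cEmbed, blockCaches = blockCaches,
                               cBody = cBody, cTail = cTail) else NULL)
}

.modelBackward <- function(dY, cache, params, cfg, ctx) {
  bTail <- .conv3Backward(dY, cache$cTail, params$tail$W, ctx$sh)
  dFf <- bTail$dX
  bBody <- .conv3Backward(dFf, cache$cBody, params$body$W, ctx$sh)
  dZ <- bBody$dX
  gBlocks <- vector("list", length(params$blocks))
  for (i in rev(seq_along(params$blocks))) {
    bb <- .blockBackward(dZ, cache$blockCaches[[i]], params$blocks[[i]],
                         cfg, ctx)
    dZ <- bb$dX
    gBlocks[[i]] <- bb$gw
  }
  dF0 <- dZ + dFf  # embed features feed both the first block and the
                   # global feature residual
  bEmbed <- .conv3Backward(dF0, cache$cEmbed, params$embed$W, ctx$sh)
  list(dX = bEmbed$dX + dY,
       gw = list(embed = list(W = bEmbed$dW, b = bEmbed$db),
                 blocks = gBlocks,
                 body = list(W = bBody$dW, b = bBody$db),
                 tail = list(W = bTail$dW, b = bTail$db)))
}
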