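# Dense-layer primitives with hand-derived backward passes.
#
# Features are stored channels-in-rows: a C x T matrix where T = batch * H*W
# and pixel columns are row-major within each image. Every forward function
# returns list(y, cache); the matching backward consumes the upstream
# gradient and the cache and returns gradients for inputs and weights.
# Correctness of the whole stack is enforced by a finite-difference
# gradient-check test.

sigmoid <- function(x) 1 / (1 + exp(-x))
siluGrad <- function(x) { s <- sigmoid(x); s * (1 + x * (1 - s)) }
softplusGrad <- function(x) sigmoid(x)

# 3x3 neighborhood index maps for a batch of H x W images laid out
# row-major with zero padding. Element k = (dr+1)*3 + (dc+1) + 1 holds the
# in-bounds destination columns (dst) and their source columns (src).
.shiftIndices <- function(H, W, batch = 1L) {
  P <- H * W
  p0 <- 0:(P - 1L)
  r <- p0 %/% W
  cc <- p0 %% W
  boff <- (0:(batch - 1L)) * P
  srcs <- vector("list", 9L)
  dsts <- vector("list", 9L)
  k <- 1L
  for (dr in -1:1) for (dc in -1:1) {
    rs <- r + dr
    cs <- cc + dc
    ok <- rs >= 0L & rs < H & cs >= 0L & cs < W
    src1 <- (rs * W + cs + 1L)[ok]
    dst1 <- which(ok)
    srcs[[k]] <- as.integer(rep(src1, times = batch) +
                              rep(boff, each = length(src1)))
    dsts[[k]] <- as.integer(rep(dst1, times = batch) +
                              rep(boff, each = length(dst1)))
    k <- k + 1L
  }
  list(srcs = srcs, dsts = dsts)
}

# ---- 3x3 convolution (zero padding, stride 1) ------------------------------
# W: Cout x (9 * Cin), offset-major column blocks; forward via im2col so
# the whole convolution is one GEMM.

.conv3Forward <- function(X, W, b, sh) {
  cols <- .im2colCpp(X, sh$srcs, sh$dsts)
  list(y = W %*% cols + b, cols = cols, Cin = nrow(X))
}

.conv3Backward <- function(dY, cache, W, sh) {
  list(dX = .col2imCpp(crossprod(W, dY), sh$srcs, sh$dsts, cache$Cin),
       dW = tcrossprod(dY, cache$cols), db = rowSums(dY))
}

# ---- depthwise 3x3 convolution ---------------------------------------------
# K: C x 9 per-channel kernels.

.dwConvForward <- function(X, K, b, sh)
  list(y = .dwConvForwardCpp(X, K, as.numeric(b), sh$srcs, sh$dsts), X = X)

.dwConvBackward <- function(dY, cache, K, sh)
  .dwConvBackwardCpp(dY, cache$X, K, sh$srcs, sh$dsts)

# ---- pointwise (1x1) projection --------------------------------------------

.pwForward <- function(X, W, b) list(y = W %*% X + b, X = X)

.pwBackward <- function(dY, cache, W)
  list(dX = crossprod(W, dY), dW = tcrossprod(dY, cache$X), db = rowSums(dY))

# ---- layer normalization over channels, per token --------------------------

.lnForward <- function(X, g, b, eps = 1e-6)
  .lnForwardCpp(X, as.numeric(g), as.numeric(b), eps)

.lnBackward <- function(dY, cache, g)
  .lnBackwardCpp(dY, cache$xhat, cache$invstd, as.numeric(g))

# ---- parameter tree utilities ----------------------------------------------

.zeroLike <- function(p) {
  if (is.list(p)) return(lapply(p, .zeroLike))
  p[] <- 0
  p
}

.flattenParams <- function(p) unlist(p, use.names = FALSE)

.refillParams <- function(p, vec, pos = 1L) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      res <- .refillParams(p[[i]], vec, pos)
      p[[i]] <- res$obj
      pos <- res$pos
    }
    return(list(obj = p, pos = pos))
  }
  n <- length(p)
  p[] <- vec[pos:(pos + n - 1L)]
  list(obj = p, pos = pos + n)
}

.unflattenParams <- function(vec, skeleton) .refillParams(skeleton, vec)$obj
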