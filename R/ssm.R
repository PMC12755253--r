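# Per-head selective state-space recurrence.
#
# Continuous-time diagonal system, zero-order-hold discretized per token:
#   A = diag(-exp(a_raw))            (strictly negative -> stable)
#   abar = exp(delta * A)            in (0, 1) for delta > 0
#   phi  = (exp(delta * A) - 1) / A  (>= 0 for delta >= 0)
#   h_t  = abar_t * h_{t-1} + phi_t * B_t * u_t
#   y_t  = C_t . h_t + D * u_t
# The step size delta_t is predicted per token by a two-layer channel MLP
# with a softplus reparameterization, so delta_t > 0 always.

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))  # overflow-safe
silu <- function(x) x / (1 + exp(-x))

#' Stability parameterization of the SSM state matrix
#'
#' Maps the unconstrained vector `aRaw` to the diagonal of the state matrix
#' `A = diag(-exp(aRaw))`, which is strictly negative for any finite input
#' and therefore yields a contractive discretized recurrence.
#'
#' @param aRaw Numeric vector of unconstrained reals.
#' @return `-exp(aRaw)`, elementwise.
#' @examples
#' makeA(c(0, log(3)))  # -1 -3
#' @export
makeA <- function(aRaw) {
  stopIfNot(all(is.finite(aRaw)), "aRaw must be finite")
  -exp(aRaw)
}

#' Predict per-token step sizes
#'
#' Applies the head's lightweight two-layer channel MLP to each token's
#' channel vector and maps the result through softplus, guaranteeing a
#' strictly positive step size.
#'
#' @param u Channel vector (length Ch) or `Ch x L` matrix of tokens.
#' @param predictor List with `W1` (`Hd x Ch`), `b1`, `W2` (`1 x Hd`), `b2`.
#' @return Positive numeric vector of step sizes, one per token.
#' @examples
#' p <- list(W1 = matrix(0, 1, 1), b1 = 0, W2 = matrix(0, 1, 1), b2 = 0)
#' predictDelta(1, p)  # softplus(0) = log(2)
#' @export
predictDelta <- function(u, predictor) {
  if (!is.matrix(u)) u <- matrix(u, ncol = 1L)
  stopIfNot(all(is.finite(u)), "non-finite input to predictDelta")
  hid <- silu(predictor$W1 %*% u + predictor$b1)
  as.vector(softplus(predictor$W2 %*% hid + predictor$b2))
}

#' Zero-order-hold discretization of a diagonal state matrix
#'
#' Computes `Abar = exp(delta * A)` and `Phi = (exp(delta * A) - 1) / A`
#' elementwise for diagonal `A < 0`. For `|delta * A|` below `1e-6` a
#' two-term Taylor expansion `Phi = delta * (1 + delta * A / 2)` replaces
#' the closed form to avoid catastrophic cancellation.
#'
#' @param delta Nonnegative scalar step size.
#' @param Adiag Numeric vector, strictly negative diagonal of A.
#' @return List with elements `Abar` and `Phi` (vectors like `Adiag`).
#' @examples
#' discretizeStep(1, -1)  # Abar = exp(-1), Phi = 1 - exp(-1)
#' @export
discretizeStep <- function(delta, Adiag) {
  stopIfNot(length(delta) == 1L && delta >= 0, "delta must be a scalar >= 0")
  stopIfNot(all(Adiag < 0), "Adiag must be strictly negative")
  x <- delta * Adiag
  abar <- exp(x)
  phi <- ifelse(abs(x) < 1e-6, delta * (1 + 0.5 * x), (abar - 1) / Adiag)
  list(Abar = abar, Phi = phi)
}

#' Construct per-head selective SSM parameters
#'
#' Bundles the trainable quantities of one scan head. In `"selective"` mode
#' the input and output projections are input-dependent,
#' `B_t = WB u_t`, `C_t = WC u_t`; in `"static"` mode fixed vectors `B`,
#' `C` are used for every token.
#'
#' @param channels Number of input channels Ch.
#' @param stateSize State dimension N per channel.
#' @param mode `"selective"` (default) or `"static"`.
#' @param aRaw,Dskip,WB,WC,B,C,delta Optional explicit components; sensible
#'   random defaults (drawn from the current RNG) are used when omitted.
#'   `delta` is a list `(W1, b1, W2, b2)`; its default bias yields initial
#'   step sizes near 0.05.
#' @param deltaHidden Hidden width of the step-size MLP.
#' @return A list of class `"SSMHeadParams"`.
#' @export
ssmHeadParams <- function(channels, stateSize = 8L,
                          mode = c("selective", "static"),
                          aRaw = NULL, Dskip = NULL, WB = NULL, WC = NULL,
                          B = NULL, C = NULL, delta = NULL,
                          deltaHidden = max(2L, channels %/% 8L)) {
  mode <- match.arg(mode)
  N <- as.integer(stateSize)
  Ch <- as.integer(channels)
  stopIfNot(N >= 1L && Ch >= 1L, "channels and stateSize must be >= 1")
  if (is.null(aRaw)) aRaw <- log(seq_len(N))
  if (is.null(Dskip)) Dskip <- rep(1, Ch)
  if (is.null(delta)) {
    delta <- list(W1 = matrix(rnorm(deltaHidden * Ch, sd = 0.02), deltaHidden, Ch),
                  b1 = rep(0, deltaHidden),
                  W2 = matrix(rnorm(deltaHidden, sd = 0.02), 1L, deltaHidden),
                  b2 = log(expm1(0.05)))
  }
  p <- list(mode = mode, stateSize = N, channels = Ch,
            aRaw = aRaw, Dskip = Dskip, delta = delta)
  if (mode == "selective") {
    if (is.null(WB)) WB <- matrix(rnorm(N * Ch, sd = 1 / sqrt(Ch)), N, Ch)
    if (is.null(WC)) WC <- matrix(rnorm(N * Ch, sd = 1 / sqrt(Ch)), N, Ch)
    p$WB <- WB; p$WC <- WC
  } else {
    if (is.null(B)) B <- rep(1, N)
    if (is.null(C)) C <- rep(1 / N, N)
    p$B <- B; p$C <- C
  }
  stopIfNot(length(p$aRaw) == N && length(p$Dskip) == Ch,
            "aRaw/Dskip dimensions inconsistent with stateSize/channels")
  class(p) <- "SSMHeadParams"
  p
}

.headProjections <- function(u, params) {
  L <- ncol(u)
  if (params$mode == "selective") {
    list(Bsel = params$WB %*% u, Csel = params$WC %*% u)
  } else {
    list(Bsel = matrix(params$B, params$stateSize, L),
         Csel = matrix(params$C, params$stateSize, L))
  }
}

#' Run the selective scan over a token sequence
#'
#' Applies the per-head recurrence to a `Ch x L` token sequence with the
#' hidden state initialized to zero. Step sizes come from the head's
#' step-size MLP via [predictDelta()].
#'
#' @param u `Ch x L` numeric matrix of serialized tokens.
#' @param params An [ssmHeadParams()] bundle with matching channel count.
#' @return `Ch x L` matrix of outputs `y`.
#' @export
selectiveScan <- function(u, params) {
  if (!is.matrix(u)) u <- matrix(u, nrow = 1L)
  stopIfNot(all(is.finite(u)), "non-finite input to selectiveScan")
  stopIfNot(nrow(u) == params$channels, "channel count mismatch")
  delta <- predictDelta(u, params$delta)
  pr <- .headProjections(u, params)
  A <- makeA(params$aRaw)
  .scanForwardCpp(u, delta, A, pr$Bsel, pr$Csel, params$Dskip,
                  seq_len(ncol(u)), 1L, FALSE)$y
}

#' Brute-force reference scan (literal per-step loop)
#'
#' Scalar-loop implementation of the same recurrence, kept deliberately
#' naive (one token, one state entry at a time, closed-form discretization)
#' as an independent check of the vectorized kernel.
#'
#' @inheritParams selectiveScan
#' @return `Ch x L` matrix of outputs.
#' @export
selectiveScanRef <- function(u, params) {
  if (!is.matrix(u)) u <- matrix(u, nrow = 1L)
  Ch <- nrow(u); L <- ncol(u); N <- params$stateSize
  A <- makeA(params$aRaw)
  y <- matrix(0, Ch, L)
  for (c in seq_len(Ch)) {
    h <- rep(0, N)
    for (t in seq_len(L)) {
      dt <- predictDelta(u[, t], params$delta)
      if (params$mode == "selective") {
        Bt <- as.vector(params$WB %*% u[, t])
        Ct <- as.vector(params$WC %*% u[, t])
      } else {
        Bt <- params$B; Ct <- params$C
      }
      for (n in seq_len(N)) {
        abar <- exp(dt * A[n])
        phi <- (abar - 1) / A[n]
        h[n] <- abar * h[n] + phi * Bt[n] * u[c, t]
      }
      y[c, t] <- sum(Ct * h) + params$Dskip[c] * u[c, t]
    }
  }
  y
}

#' Multi-head selective scan over a feature grid
#'
#' Runs m parallel selective scans, one head per scan order: each head
#' serializes the grid along its order, scans, and deserializes through the
#' inverse order. Head outputs are concatenated channelwise, optionally
#' layer-normalized and multiplicatively gated, then linearly projected to
#' the model dimension. The default projection is the head-wise mean, so
#' output channels equal input channels.
#'
#' @param features `C x H x W` array (or `H x W` matrix, treated as one
#'   channel).
#' @param scanSet A [ScanSet-class] matching the grid size.
#' @param heads List of [ssmHeadParams()], one per scan order.
#' @param ln `NULL` (skip), `TRUE` (unit-affine layer norm over the
#'   concatenated channels) or a list `(g, b)` of affine parameters.
#' @param gate Optional `C x (H*W)` multiplicative gate, tiled across
#'   heads, or `NULL`.
#' @param proj Optional projection `list(W, b)` with `W` of shape
#'   `C_out x (m*C)`; `NULL` uses the head-mean merge.
#' @return Feature grid with spatial dimensions equal to the input.
#' @export
multiHeadScan <- function(features, scanSet, heads, ln = NULL, gate = NULL,
                          proj = NULL) {
  if (is.matrix(features)) features <- array(features, c(1L, dim(features)))
  C <- dim(features)[1]
  stopIfNot(length(heads) == scanSet@scanCount,
            "need exactly one head per scan order")
  orders <- scanSet@orders
  P <- orders[[1]]@height * orders[[1]]@width
  m <- length(heads)
  mat <- .gridToMat(features)
  Ycat <- matrix(0, m * C, P)
  for (j in seq_len(m)) {
    hp <- heads[[j]]
    delta <- predictDelta(mat, hp$delta)
    pr <- .headProjections(mat, hp)
    Ycat[(j - 1L) * C + seq_len(C), ] <-
      .scanForwardCpp(mat, delta, makeA(hp$aRaw), pr$Bsel, pr$Csel,
                      hp$Dskip, orders[[j]]@order + 1L, 1L, FALSE)$y
  }
  if (!is.null(ln)) {
    if (isTRUE(ln)) ln <- list(g = rep(1, m * C), b = rep(0, m * C))
    Ycat <- .lnForward(Ycat, ln$g, ln$b)$y
  }
  if (!is.null(gate)) {
    if (!is.matrix(gate)) gate <- matrix(gate, C, P)
    Ycat <- Ycat * gate[rep(seq_len(C), m), , drop = FALSE]
  }
  if (is.null(proj)) {
    W <- matrix(0, C, m * C)
    for (j in seq_len(m)) W[, (j - 1L) * C + seq_len(C)] <-
        diag(1 / m, C)
    proj <- list(W = W, b = rep(0, C))
  }
  out <- proj$W %*% Ycat + proj$b
  .matToGrid(out, orders[[1]]@height, orders[[1]]@width)
}
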