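# Public architecture API: configs, model construction, accounting, and the
# standalone block-level operations.

#' Create a model configuration
#'
#' The default configuration is the baseline network: four stages repeated
#' `c(4, 6, 6, 7)` times, channel-MLP expansion `alpha = 2`, hybrid
#' diagonal scanning with 8 paths and one selective-scan head per path.
#' The default width `embedDim = 46` is derived from the parameter budget:
#' it is the largest even width whose full configuration stays below 0.9
#' million trainable parameters (see [countParameters()]).
#'
#' @param stageRepeats Integer vector of length 4, blocks per stage.
#' @param embedDim Channel width D.
#' @param alpha Channel-MLP expansion factor; `alpha * embedDim` must be
#'   even.
#' @param scanType `"diagonal"` or `"zigzag"`.
#' @param scanCount 8 or 4 scan paths.
#' @param stateSize SSM state size N per head.
#' @param heads Number of heads m; defaults to `scanCount` (one head per
#'   scan path).
#' @param upsampleFactor Nominal SR factor (metadata; the network is
#'   grid-preserving on pre-resampled inputs).
#' @param selectiveBC Input-dependent B/C projections (default) or static.
#' @param gated SiLU-gated multiplicative merge (default on).
#' @param seed Seed for parameter initialization.
#' @return A [ModelConfig-class].
#' @export
modelConfig <- function(stageRepeats = c(4L, 6L, 6L, 7L), embedDim = 46L,
                        alpha = 2, scanType = c("diagonal", "zigzag"),
                        scanCount = 8L, stateSize = 8L, heads = scanCount,
                        upsampleFactor = 4, selectiveBC = TRUE, gated = TRUE,
                        seed = 1L) {
  scanType <- match.arg(scanType)
  new("ModelConfig",
      stageRepeats = as.integer(stageRepeats), embedDim = as.integer(embedDim),
      alpha = as.numeric(alpha), scanType = scanType,
      scanCount = as.integer(scanCount), stateSize = as.integer(stateSize),
      heads = as.integer(heads), upsampleFactor = as.numeric(upsampleFactor),
      selectiveBC = isTRUE(selectiveBC), gated = isTRUE(gated),
      seed = as.integer(seed))
}

.cfgList <- function(cfg) {
  list(stageRepeats = cfg@stageRepeats, embedDim = cfg@embedDim,
       alpha = cfg@alpha, scanType = cfg@scanType, scanCount = cfg@scanCount,
       stateSize = cfg@stateSize, heads = cfg@heads,
       upsampleFactor = cfg@upsampleFactor, selectiveBC = cfg@selectiveBC,
       gated = cfg@gated, seed = cfg@seed)
}

.configFromList <- function(x) {
  do.call(modelConfig, x)
}

#' Build a super-resolution model
#'
#' Instantiates the MambaFormer network for a [ModelConfig-class]:
#' a 3x3 embedding convolution (1 -> D), `sum(stageRepeats)` pre-norm
#' MambaFormer blocks, a 3x3 body convolution with a global feature
#' residual from the embedding output, and a 3x3 projection to the image
#' channel with a global image residual. Residual-branch output layers
#' (block output projections, body and tail convolutions) are
#' zero-initialized, so a freshly built model is exactly the identity map
#' on images; remaining weights are drawn from `N(0, 0.02^2)` under the
#' config seed.
#'
#' @param config A [ModelConfig-class].
#' @return An [SRModel-class].
#' @examples
#' m <- buildModel(modelConfig(stageRepeats = c(1, 1, 1, 1), embedDim = 8,
#'                             scanCount = 4, stateSize = 2))
#' countParameters(m)
#' @export
buildModel <- function(config) {
  validObject(config)
  params <- .initParams(config)
  new("SRModel", config = config, params = params,
      scanSet = list(scanType = config@scanType, scanCount = config@scanCount),
      meta = list(seed = config@seed))
}

#' Zero the residual-branch output layers of a model
#'
#' Sets every block's output projections and the body and tail convolutions
#' to zero, making the network the exact identity map on images. Useful as
#' a reference point: the model output then equals its (pre-resampled)
#' input bit for bit.
#'
#' @param model An [SRModel-class].
#' @return The modified model.
#' @export
zeroResidualInit <- function(model) {
  model@params <- .zeroResidual(model@params)
  model
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars in a model or parameter tree. The
#' default configuration stays below the 0.9 million parameter budget.
#'
#' @param object An [SRModel-class] or a nested parameter list.
#' @return Integer count.
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' @rdname countParameters
#' @export
setMethod("countParameters", "SRModel",
          function(object) countParameters(object@params))

#' @rdname countParameters
#' @export
setMethod("countParameters", "list", function(object) {
  if (is.list(object)) return(sum(vapply(object, countParameters, numeric(1))))
  0
})

setMethod("countParameters", "ANY",
          function(object) if (is.numeric(object)) length(object) else 0L)

#' Analytic multiply-accumulate estimate
#'
#' Counts multiply-accumulate operations (MACs) of one forward pass at a
#' given input size: convolutions, pointwise projections, layer norms,
#' gating, the per-head step-size MLP and B/C projections, and the scan
#' recurrence (O(N) per channel per token). The estimate is linear in the
#' pixel count by construction.
#'
#' @param config A [ModelConfig-class].
#' @param inputShape `c(H, W)` of the input slice.
#' @param blocks Number of MambaFormer blocks; defaults to
#'   `sum(stageRepeats(config))`. `blocks = 0` gives the embed/body/tail
#'   convolution cost alone.
#' @return Estimated MAC count (numeric).
#' @export
estimateFlops <- function(config, inputShape,
                          blocks = sum(config@stageRepeats)) {
  P <- prod(inputShape)
  D <- config@embedDim
  m <- config@heads
  N <- config@stateSize
  hd <- max(2L, D %/% 8L)
  aD <- round(config@alpha * D)
  perTokenBlock <-
    5 * D +                       # ln1
    D * D +                       # input projection
    (if (config@gated) D * D + m * D else 0) +  # gate branch + multiply
    9 * D +                       # depthwise conv
    m * (hd * D + hd +            # step-size MLP
         2 * N * D +              # selective B/C projections
         2 * N +                  # discretization exp/phi
         3 * N * D) +             # recurrence + output contraction
    5 * m * D +                   # merge layer norm
    m * D * D +                   # output projection
    5 * D +                       # ln2
    D * aD + aD / 2 + (aD / 2) * D  # channel MLP
  headTail <- 9 * D +             # embed conv (1 -> D)
    9 * D * D +                   # body conv
    9 * D                         # tail conv (D -> 1)
  P * (blocks * perTokenBlock + headTail)
}

#' Ablation configuration factory
#'
#' Named presets of the ablation study: `baseline` (stages `[4,6,6,7]`,
#' `alpha = 2`, diagonal scanning with 8 paths, composite loss
#' `4 * L1 + Lp`), `blocks_light` (`[3,4,4,5]`), `block_heavy`
#' (`[5,7,7,8]`), `scan4` (4 scan paths), `zigzag_scan` (zigzag orders,
#' 8 paths), `alpha1` (`alpha = 1`) and `l1_only` (perceptual term off).
#'
#' @param name Preset name.
#' @return List with elements `name`, `config` ([ModelConfig-class]) and
#'   `loss` ([lossConfig()]).
#' @export
makeAblationConfig <- function(name = c("baseline", "blocks_light",
                                        "block_heavy", "scan4", "zigzag_scan",
                                        "alpha1", "l1_only")) {
  name <- match.arg(name)
  cfg <- switch(name,
    baseline = modelConfig(),
    blocks_light = modelConfig(stageRepeats = c(3L, 4L, 4L, 5L)),
    block_heavy = modelConfig(stageRepeats = c(5L, 7L, 7L, 8L)),
    scan4 = modelConfig(scanCount = 4L, heads = 4L),
    zigzag_scan = modelConfig(scanType = "zigzag"),
    alpha1 = modelConfig(alpha = 1),
    l1_only = modelConfig()
  )
  loss <- lossConfig(usePerceptual = name != "l1_only")
  list(name = name, config = cfg, loss = loss)
}

# ---- standalone block-level operations -------------------------------------

#' Construct channel-MLP parameters
#'
#' @param C Input channel count.
#' @param alpha Expansion factor; `alpha * C` must be even.
#' @param Win,bin,Wout,bout Optional explicit weights (`Win`:
#'   `(alpha*C) x C`, `Wout`: `C x (alpha*C/2)`).
#' @return Parameter list for [channelMLP()].
#' @export
channelMLPParams <- function(C, alpha = 2, Win = NULL, bin = NULL,
                             Wout = NULL, bout = NULL) {
  aC <- round(alpha * C)
  stopIfNot(aC %% 2 == 0, "alpha * C must be even")
  if (is.null(Win)) Win <- matrix(rnorm(aC * C, sd = 0.02), aC, C)
  if (is.null(bin)) bin <- rep(0, aC)
  if (is.null(Wout)) Wout <- matrix(rnorm(C * aC / 2, sd = 0.02), C, aC %/% 2L)
  if (is.null(bout)) bout <- rep(0, C)
  stopIfNot(nrow(Win) == aC && ncol(Win) == C &&
              nrow(Wout) == C && ncol(Wout) == aC %/% 2L,
            "channel MLP weight shapes inconsistent with C and alpha")
  list(C = C, alpha = alpha,
       inp = list(W = Win, b = bin), out = list(W = Wout, b = bout))
}

#' Gated channel MLP
#'
#' Pointwise 1x1 expansion to `alpha * C` channels, split into halves,
#' elementwise multiplicative gating, and 1x1 projection back to C
#' channels. Spatial dimensions are unchanged.
#'
#' @param x `C x H x W` array or `C x P` matrix of features.
#' @param params A [channelMLPParams()] list.
#' @return Features of the same shape as `x`.
#' @export
channelMLP <- function(x, params) {
  wasArr <- !is.matrix(x) && length(dim(x)) == 3L
  m <- if (wasArr) .gridToMat(x) else x
  stopIfNot(nrow(m) == params$C, "channel count mismatch")
  y <- .mlpForward(m, params, train = FALSE)$y
  if (wasArr) .matToGrid(y, dim(x)[2], dim(x)[3]) else y
}

#' Construct MHSSM module weights
#'
#' @param D Model channel width.
#' @param m Number of heads (= scan paths).
#' @param stateSize SSM state size N.
#' @param selectiveBC,gated As in [modelConfig()].
#' @return Weight list for [mhssmModule()].
#' @export
mhssmWeights <- function(D, m = 8L, stateSize = 8L, selectiveBC = TRUE,
                         gated = TRUE) {
  hd <- max(2L, D %/% 8L)
  w <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
  out <- list(
    inp = list(W = w(D, D), b = rep(0, D)),
    dw = list(K = w(D, 9L), b = rep(0, D)),
    heads = lapply(seq_len(m), function(j)
      .initHeadParams(D, as.integer(stateSize), hd, selectiveBC)),
    lnm = list(g = rep(1, m * D), b = rep(0, m * D)),
    out = list(W = w(D, m * D), b = rep(0, D))
  )
  if (gated) out$gate <- list(W = w(D, D), b = rep(0, D))
  out
}

.cfgForWeights <- function(w, scanSet) {
  h1 <- w$heads[[1]]
  # scanCount slot must be a standard preset; the actual orders come from
  # the supplied scan set, so a custom count only affects the head loop
  sc <- if (scanSet@scanCount %in% c(4L, 8L)) scanSet@scanCount else 8L
  modelConfig(stageRepeats = c(1L, 1L, 1L, 1L), embedDim = nrow(w$inp$W),
              scanType = scanSet@scanType, scanCount = sc,
              stateSize = length(h1$aRaw), heads = length(w$heads),
              selectiveBC = !is.null(h1$WB), gated = !is.null(w$gate))
}

#' Multi-head selective state-space module
#'
#' Linear projection, depthwise 3x3 convolution, SiLU, multi-head
#' selective scan over the scan set, merge (layer norm, optional SiLU
#' gate), and linear projection back to the model dimension. Spatial shape
#' is preserved.
#'
#' @param x `C x H x W` array of features (C = model width D).
#' @param weights A [mhssmWeights()] list.
#' @param scanSet Optional [ScanSet-class]; defaults to the diagonal set
#'   sized for the number of heads and the grid of `x`.
#' @return `C x H x W` array.
#' @export
mhssmModule <- function(x, weights, scanSet = NULL) {
  stopIfNot(length(dim(x)) == 3L, "x must be a C x H x W array")
  H <- dim(x)[2]; W <- dim(x)[3]
  stopIfNot(dim(x)[1] == nrow(weights$inp$W), "channel width mismatch")
  if (is.null(scanSet))
    scanSet <- buildScanSet(H, W, "diagonal",
                            if (length(weights$heads) == 4L) 4L else 8L)
  cfg <- .cfgForWeights(weights, scanSet)
  ctx <- .modelContext(cfg, H, W, 1L, scanSet)
  y <- .attnForward(.gridToMat(x), weights, cfg, ctx, train = FALSE)$y
  .matToGrid(y, H, W)
}

#' One MambaFormer block
#'
#' Pre-norm residual block: `z' = z + MHSSM(LN(z))`, then
#' `z'' = z' + ChannelMLP(LN(z'))`.
#'
#' @param z `C x H x W` input features.
#' @param weights List with `ln1`, `attn` ([mhssmWeights()] format), `ln2`,
#'   `mlp` (`inp`/`out` pointwise layers), as produced inside
#'   [buildModel()].
#' @param scanSet Optional [ScanSet-class] (see [mhssmModule()]).
#' @return `C x H x W` output features.
#' @export
mambaformerBlock <- function(z, weights, scanSet = NULL) {
  stopIfNot(length(dim(z)) == 3L, "z must be a C x H x W array")
  H <- dim(z)[2]; W <- dim(z)[3]
  if (is.null(scanSet))
    scanSet <- buildScanSet(H, W, "diagonal",
                            if (length(weights$attn$heads) == 4L) 4L else 8L)
  cfg <- .cfgForWeights(weights$attn, scanSet)
  ctx <- .modelContext(cfg, H, W, 1L, scanSet)
  y <- .blockForward(.gridToMat(z), weights, cfg, ctx, train = FALSE)$y
  .matToGrid(y, H, W)
}

# ---- checkpointing ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is a flat named-tensor archive (RDS) holding the
#' parameter tree and metadata, with a JSON config sidecar
#' (`<path>.json`) for tool-agnostic inspection. Round-trips are
#' bit-exact.
#'
#' @param model An [SRModel-class].
#' @param path Destination file.
#' @return `loadCheckpoint` returns the restored [SRModel-class].
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(params = model@params, config = .cfgList(model@config),
               scanSet = model@scanSet, meta = model@meta), path)
  jsonlite::write_json(.cfgList(model@config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  stopIfNot(file.exists(path), paste("checkpoint not found:", path))
  x <- readRDS(path)
  new("SRModel", config = .configFromList(x$config), params = x$params,
      scanSet = x$scanSet, meta = x$meta)
}
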