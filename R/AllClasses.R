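#' ScanOrder: a bijective traversal of an H x W token grid
#'
#' A `ScanOrder` records one serialization of a 2D token grid into a 1D
#' sequence: the visitation order (0-based, row-major cell indices) together
#' with its inverse, the grid dimensions, the traversal kind and the
#' direction. Cell `(r, c)` (0-based) has row-major index `r * W + c`.
#'
#' @slot height Integer, number of grid rows (H >= 1).
#' @slot width Integer, number of grid columns (W >= 1).
#' @slot kind One of `"horizontal"`, `"vertical"`, `"antidiagonal"`,
#'   `"maindiagonal"`, `"zigzag"`.
#' @slot direction `"forward"` or `"reverse"`.
#' @slot order Integer vector of length `H * W`: the t-th visited cell.
#' @slot inverse Integer vector of length `H * W`: position in the sequence
#'   at which each cell is visited, so `inverse[order[t] + 1] == t - 1`
#'   in 0-based terms.
#'
#' @seealso [buildScanOrder()], [buildScanSet()], [serializeGrid()]
#' @export
setClass("ScanOrder",
  representation(
    height = "integer", width = "integer",
    kind = "character", direction = "character",
    order = "integer", inverse = "integer"
  )
)

setValidity("ScanOrder", function(object) {
  n <- object@height * object@width
  msgs <- character(0)
  if (length(object@height) != 1L || object@height < 1L)
    msgs <- c(msgs, "height must be a positive integer")
  if (length(object@width) != 1L || object@width < 1L)
    msgs <- c(msgs, "width must be a positive integer")
  if (!object@kind %in% .scanKinds)
    msgs <- c(msgs, "unknown scan kind")
  if (!object@direction %in% .scanDirections)
    msgs <- c(msgs, "unknown scan direction")
  if (length(object@order) != n || length(object@inverse) != n) {
    msgs <- c(msgs, "order/inverse length must equal height * width")
  } else if (n > 0L) {
    if (!identical(sort(object@order), 0:(n - 1L)))
      msgs <- c(msgs, "order is not a permutation of 0..n-1")
    else if (!all(object@inverse[object@order + 1L] == 0:(n - 1L)))
      msgs <- c(msgs, "inverse does not invert order")
  }
  if (length(msgs)) msgs else TRUE
})

#' ScanSet: the collection of scan orders used by the multi-head scanner
#'
#' Groups several [ScanOrder-class] traversals over a common grid. The
#' default hybrid set factorizes as four kinds (horizontal, vertical and the
#' two diagonal kinds, or zigzag variants) times two directions.
#'
#' @slot orders List of [ScanOrder-class] objects sharing one grid size.
#' @slot scanType `"diagonal"` or `"zigzag"`.
#' @slot scanCount Integer, number of scan paths (4 or 8).
#'
#' @seealso [buildScanSet()], [multiHeadScan()]
#' @export
setClass("ScanSet",
  representation(orders = "list", scanType = "character", scanCount = "integer")
)

setValidity("ScanSet", function(object) {
  msgs <- character(0)
  if (!object@scanType %in% .scanTypes) msgs <- c(msgs, "unknown scanType")
  if (object@scanCount != length(object@orders))
    msgs <- c(msgs, "scanCount must equal length(orders)")
  if (!all(vapply(object@orders, is, logical(1), class2 = "ScanOrder")))
    msgs <- c(msgs, "orders must all be ScanOrder objects")
  else if (length(object@orders) > 1L) {
    hs <- vapply(object@orders, function(o) o@height, integer(1))
    ws <- vapply(object@orders, function(o) o@width, integer(1))
    if (length(unique(hs)) != 1L || length(unique(ws)) != 1L)
      msgs <- c(msgs, "all orders must share the same grid dimensions")
  }
  if (length(msgs)) msgs else TRUE
})

#' ModelConfig: hyperparameters of the MambaFormer super-resolution network
#'
#' @slot stageRepeats Integer vector of length 4: block repetitions per
#'   stage (default `c(4, 6, 6, 7)`).
#' @slot embedDim Model channel width D.
#' @slot alpha Channel-MLP expansion factor (alpha * D must be even).
#' @slot scanType `"diagonal"` or `"zigzag"`.
#' @slot scanCount Number of scan paths (4 or 8); the head count m is tied
#'   to it.
#' @slot stateSize Per-head SSM state size N.
#' @slot heads Number of selective-scan heads m (must divide embedDim).
#' @slot upsampleFactor Nominal spatial super-resolution factor; the
#'   network itself is grid-preserving (inputs are pre-resampled to the HR
#'   grid), so this is provenance metadata.
#' @slot selectiveBC Logical; if `TRUE` the SSM input/output projections B
#'   and C are input-dependent (selective), else static per head.
#' @slot gated Logical; SiLU-gated multiplicative merge branch in the MHSSM
#'   module.
#' @slot seed RNG seed used for parameter initialization.
#'
#' @seealso [modelConfig()], [makeAblationConfig()], [buildModel()]
#' @export
setClass("ModelConfig",
  representation(
    stageRepeats = "integer", embedDim = "integer", alpha = "numeric",
    scanType = "character", scanCount = "integer", stateSize = "integer",
    heads = "integer", upsampleFactor = "numeric",
    selectiveBC = "logical", gated = "logical", seed = "integer"
  )
)

setValidity("ModelConfig", function(object) {
  msgs <- character(0)
  if (length(object@stageRepeats) != 4L || any(object@stageRepeats < 1L))
    msgs <- c(msgs, "stageRepeats must be 4 positive integers")
  if (object@embedDim < 1L) msgs <- c(msgs, "embedDim must be positive")
  if (!object@scanType %in% .scanTypes) msgs <- c(msgs, "unknown scanType")
  if (!object@scanCount %in% c(4L, 8L)) msgs <- c(msgs, "scanCount must be 4 or 8")
  if (object@stateSize < 1L) msgs <- c(msgs, "stateSize must be >= 1")
  if (object@heads < 1L) msgs <- c(msgs, "heads must be >= 1")
  if (abs(object@alpha * object@embedDim -
          round(object@alpha * object@embedDim / 2) * 2) > 1e-9)
    msgs <- c(msgs, "alpha * embedDim must be even")
  if (length(msgs)) msgs else TRUE
})

#' SRModel: a parameterized super-resolution network
#'
#' Bundles a [ModelConfig-class] with the flat named list of parameter
#' tensors of the network. Use [buildModel()] to construct one,
#' [countParameters()] for its size, [predict()][predictSlice] or
#' [predictSlice()] for inference and [trainModel()] to fit it.
#'
#' @slot config A [ModelConfig-class].
#' @slot params Named list of numeric arrays (the trainable tensors).
#' @slot scanSet The [ScanSet-class] kinds used by every block (orders are
#'   instantiated lazily per input grid size).
#' @slot meta List of provenance fields (seed, training history, ...).
#' @export
setClass("SRModel",
  representation(config = "ModelConfig", params = "list",
                 scanSet = "list", meta = "list")
)

setMethod("show", "ScanOrder", function(object) {
  cat(sprintf("ScanOrder %dx%d %s/%s\n", object@height, object@width,
              object@kind, object@direction))
  n <- length(object@order)
  head_n <- min(n, 12L)
  cat(" order:", paste(object@order[seq_len(head_n)], collapse = " "),
      if (n > head_n) "..." else "", "\n")
})

setMethod("show", "ScanSet", function(object) {
  o <- object@orders[[1]]
  cat(sprintf("ScanSet of %d orders on %dx%d grid (scanType=%s)\n",
              object@scanCount, o@height, o@width, object@scanType))
  for (ord in object@orders)
    cat(sprintf("  - %s/%s\n", ord@kind, ord@direction))
})

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig\n")
  cat(sprintf("  stages      : [%s]\n", paste(object@stageRepeats, collapse = ", ")))
  cat(sprintf("  embedDim    : %d\n", object@embedDim))
  cat(sprintf("  alpha       : %g\n", object@alpha))
  cat(sprintf("  scan        : %s x %d paths, %d heads, state N=%d\n",
              object@scanType, object@scanCount, object@heads, object@stateSize))
  cat(sprintf("  selective BC: %s, gated merge: %s\n",
              object@selectiveBC, object@gated))
})

setMethod("show", "SRModel", function(object) {
  cat("SRModel (MambaFormer super-resolution network)\n")
  show(object@config)
  cat(sprintf("  parameters  : %s\n",
              format(countParameters(object), big.mark = ",")))
})

# ---- accessors -------------------------------------------------------------

#' @rdname ScanOrder-class
#' @param object,x A `ScanOrder` (or `ScanSet` for [scanOrders()]).
#' @export
scanIndices <- function(x) x@order

#' @rdname ScanOrder-class
#' @export
scanInverse <- function(x) x@inverse

#' @rdname ScanOrder-class
#' @export
gridDim <- function(x) c(x@height, x@width)

#' @rdname ScanOrder-class
#' @export
scanKind <- function(x) x@kind

#' @rdname ScanOrder-class
#' @export
scanDirection <- function(x) x@direction

#' @rdname ScanSet-class
#' @param x A `ScanSet`.
#' @export
scanOrders <- function(x) x@orders

#' @rdname ModelConfig-class
#' @param x A `ModelConfig` or `SRModel`.
#' @export
modelConfigOf <- function(x) if (is(x, "SRModel")) x@config else x

#' @rdname ModelConfig-class
#' @export
stageRepeats <- function(x) modelConfigOf(x)@stageRepeats

#' @rdname ModelConfig-class
#' @export
embedDim <- function(x) modelConfigOf(x)@embedDim

#' @rdname SRModel-class
#' @param x An `SRModel`.
#' @export
modelParams <- function(x) x@params
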