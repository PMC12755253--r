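# Scan-order construction for serializing 2D token grids.
#
# Cells are indexed row-major and 0-based: cell (r, c) has id r * W + c.
# Raster (horizontal) scanning places diagonal neighbors far apart in the
# sequence ("pixel forgetting"); diagonal traversals keep cells of one
# anti-diagonal consecutive, so diagonally adjacent pixels stay adjacent in
# the scanned sequence.

.antidiagCells <- function(height, width) {
  out <- integer(height * width)
  k <- 1L
  for (d in 0:(height + width - 2L)) {
    rs <- max(0L, d - width + 1L):min(d, height - 1L)
    for (r in rs) {
      out[k] <- r * width + (d - r)
      k <- k + 1L
    }
  }
  out
}

.zigzagCells <- function(height, width) {
  out <- integer(height * width)
  k <- 1L
  for (d in 0:(height + width - 2L)) {
    rs <- max(0L, d - width + 1L):min(d, height - 1L)
    if (d %% 2L == 0L) rs <- rev(rs)  # even anti-diagonals walk upward
    for (r in rs) {
      out[k] <- r * width + (d - r)
      k <- k + 1L
    }
  }
  out
}

.mirrorCells <- function(order, width) {
  # reflect each visited cell across the vertical axis: (r, c) -> (r, W-1-c)
  r <- order %/% width
  c <- order %% width
  r * width + (width - 1L - c)
}

#' Build a scan order over an H x W token grid
#'
#' Constructs one of the serialization orders used by the hybrid selective
#' scanning strategy: raster (`horizontal`), column-major (`vertical`),
#' anti-diagonal (`antidiagonal`; anti-diagonals `d = r + c` in increasing
#' `d`, increasing row within each diagonal), main-diagonal
#' (`maindiagonal`; the anti-diagonal order of the horizontally mirrored
#' grid, mirrored back) and JPEG-style `zigzag` (anti-diagonals with
#' alternating traversal direction). `direction = "reverse"` reverses the
#' forward visitation order.
#'
#' @param height,width Grid dimensions (positive integers).
#' @param kind One of `"horizontal"`, `"vertical"`, `"antidiagonal"`,
#'   `"maindiagonal"`, `"zigzag"`.
#' @param direction `"forward"` (default) or `"reverse"`.
#' @return A [ScanOrder-class] object.
#' @examples
#' buildScanOrder(3, 3, "antidiagonal")
#' scanIndices(buildScanOrder(2, 2, "vertical"))  # 0 2 1 3
#' @export
buildScanOrder <- function(height, width,
                           kind = c("horizontal", "vertical", "antidiagonal",
                                    "maindiagonal", "zigzag"),
                           direction = c("forward", "reverse")) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  stopIfNot(length(height) == 1L && length(width) == 1L &&
              height >= 1 && width >= 1 &&
              height == as.integer(height) && width == as.integer(width),
            "height and width must be positive integers")
  height <- as.integer(height); width <- as.integer(width)
  order <- switch(kind,
    horizontal = 0:(height * width - 1L),
    vertical = as.integer(as.vector(outer(0:(height - 1L) * width,
                                          0:(width - 1L), `+`))),
    antidiagonal = .antidiagCells(height, width),
    maindiagonal = .mirrorCells(.antidiagCells(height, width), width),
    zigzag = .zigzagCells(height, width)
  )
  if (direction == "reverse") order <- rev(order)
  new("ScanOrder", height = height, width = width, kind = kind,
      direction = direction, order = as.integer(order),
      inverse = invertOrder(order))
}

#' Invert a permutation
#'
#' Given a 0-based permutation `order` of `0..n-1`, returns the 0-based
#' inverse `o` with `o[order[t] + 1] == t - 1` (1-based indexing into the
#' vectors); i.e. the sequence position at which each cell is visited.
#'
#' @param order Integer vector, a permutation of `0..n-1`.
#' @return Integer vector of the same length.
#' @examples
#' invertOrder(c(2, 0, 1))  # 1 2 0
#' @export
invertOrder <- function(order) {
  n <- length(order)
  order <- as.integer(order)
  stopIfNot(n > 0L && !anyNA(order) && min(order) == 0L && max(order) == n - 1L &&
              !anyDuplicated(order),
            "order must be a permutation of 0..n-1")
  inv <- integer(n)
  inv[order + 1L] <- 0:(n - 1L)
  inv
}

#' Build the hybrid scan set
#'
#' Assembles the multi-path scan set fed to the multi-head selective
#' scanner. With `scanType = "diagonal"` and `scanCount = 8` the set is the
#' four kinds (horizontal, vertical, antidiagonal, maindiagonal) crossed
#' with both directions; `scanType = "zigzag"` substitutes the zigzag order
#' and its horizontally mirrored variant for the two diagonal kinds.
#' `scanCount = 4` keeps the forward direction of each kind only, so every
#' scan family stays represented.
#'
#' @param height,width Grid dimensions.
#' @param scanType `"diagonal"` (default) or `"zigzag"`.
#' @param scanCount 8 (default) or 4.
#' @return A [ScanSet-class].
#' @examples
#' buildScanSet(4, 4, "diagonal", 8)
#' @export
buildScanSet <- function(height, width, scanType = c("diagonal", "zigzag"),
                         scanCount = 8L) {
  scanType <- match.arg(scanType)
  stopIfNot(scanCount %in% c(4L, 8L), "scanCount must be 4 or 8")
  scanCount <- as.integer(scanCount)
  mk <- function(kind, direction) buildScanOrder(height, width, kind, direction)
  mkMirrorZig <- function(direction) {
    base <- buildScanOrder(height, width, "zigzag", "forward")
    ord <- .mirrorCells(base@order, base@width)
    if (direction == "reverse") ord <- rev(ord)
    new("ScanOrder", height = base@height, width = base@width,
        kind = "zigzag", direction = direction,
        order = as.integer(ord), inverse = invertOrder(ord))
  }
  dirs <- if (scanCount == 8L) c("forward", "reverse") else "forward"
  orders <- list()
  for (dir in dirs) {
    orders <- c(orders, list(mk("horizontal", dir), mk("vertical", dir)))
    if (scanType == "diagonal") {
      orders <- c(orders, list(mk("antidiagonal", dir), mk("maindiagonal", dir)))
    } else {
      orders <- c(orders, list(mk("zigzag", dir), mkMirrorZig(dir)))
    }
  }
  new("ScanSet", orders = orders, scanType = scanType, scanCount = scanCount)
}

# row-major [C, HW] matrix view of a C x H x W array
.gridToMat <- function(x) {
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  stopIfNot(length(dim(x)) == 3L, "features must be C x H x W (or H x W)")
  matrix(aperm(x, c(1L, 3L, 2L)), nrow = dim(x)[1])
}

.matToGrid <- function(m, height, width, drop = FALSE) {
  a <- aperm(array(m, c(nrow(m), width, height)), c(1L, 3L, 2L))
  if (drop && dim(a)[1] == 1L) a <- array(a, c(height, width))
  a
}

#' Serialize / deserialize a token grid along a scan order
#'
#' `serializeGrid()` rearranges a `C x H x W` feature grid (or a plain
#' `H x W` matrix) into a `C x (H*W)` token sequence following a
#' [ScanOrder-class]; `deserializeGrid()` is its exact inverse.
#'
#' @param features `C x H x W` array or `H x W` matrix.
#' @param seq `C x (H*W)` matrix (or vector for a single channel).
#' @param order A [ScanOrder-class] whose grid matches the features.
#' @param drop For `deserializeGrid`, drop a singleton channel dimension.
#' @return `serializeGrid`: a `C x (H*W)` matrix (plain vector if the input
#'   was a matrix); `deserializeGrid`: the reconstructed grid.
#' @examples
#' o <- buildScanOrder(2, 2, "vertical")
#' serializeGrid(matrix(1:4, 2, byrow = TRUE), o)  # 1 3 2 4
#' @export
serializeGrid <- function(features, order) {
  wasMat <- is.matrix(features)
  m <- .gridToMat(features)
  d <- if (wasMat) dim(features) else dim(features)[2:3]
  stopIfNot(d[1] == order@height && d[2] == order@width,
            "feature grid dimensions do not match the scan order")
  out <- m[, order@order + 1L, drop = FALSE]
  if (wasMat) as.vector(out) else out
}

#' @rdname serializeGrid
#' @export
deserializeGrid <- function(seq, order, drop = FALSE) {
  if (!is.matrix(seq)) seq <- matrix(seq, nrow = 1L)
  n <- order@height * order@width
  stopIfNot(ncol(seq) == n, "sequence length does not match the scan order")
  m <- matrix(0, nrow(seq), n)
  m[, order@order + 1L] <- seq
  .matToGrid(m, order@height, order@width, drop = drop || nrow(seq) == 1L)
}
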