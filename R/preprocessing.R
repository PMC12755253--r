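# Volume preprocessing: percentile intensity normalization, image-domain
# degradation by linear interpolation, slice selection, NIfTI I/O and
# masking. The slicing axis is the volume's third axis throughout.

#' Percentile intensity normalization
#'
#' Rescales a volume to `[0, 1]` using its low/high percentiles (defaults
#' 1st and 99th) to suppress outliers:
#' `v' = clip((v - P_low) / (P_high - P_low), 0, 1)`. With a mask the
#' percentiles are computed over foreground (mask > 0) voxels only;
#' otherwise over all voxels. Percentiles use linear interpolation between
#' order statistics.
#'
#' @param volume Numeric array (any dimensionality).
#' @param pLow,pHigh Percentiles in `[0, 100]`.
#' @param mask Optional array of the same shape; nonzero marks foreground.
#' @return Normalized array in `[0, 1]`.
#' @export
percentileNormalize <- function(volume, pLow = 1, pHigh = 99, mask = NULL) {
  vals <- if (is.null(mask)) as.vector(volume) else volume[mask > 0]
  stopIfNot(length(unique(vals)) > 1L, "degenerate input: constant volume")
  qs <- quantile(vals, c(pLow, pHigh) / 100, names = FALSE, type = 7)
  stopIfNot(qs[2] > qs[1],
            "degenerate input: equal low/high percentiles")
  out <- (volume - qs[1]) / (qs[2] - qs[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# center-aligned separable linear resampling along one axis
.resampleAxis <- function(x, axis, nNew) {
  d <- dim(x)
  nOld <- d[axis]
  if (nNew == nOld) return(x)
  scale <- nOld / nNew
  pos <- ((seq_len(nNew) - 0.5) * scale) - 0.5  # 0-based source coordinate
  pos <- pmin(pmax(pos, 0), nOld - 1)
  lo <- if (nOld > 1L) pmin(floor(pos), nOld - 2) else rep(0, nNew)
  w <- pos - lo
  perm <- c(axis, seq_along(d)[-axis])
  xp <- aperm(x, perm)
  mat <- matrix(xp, nrow = nOld)
  lower <- mat[lo + 1L, , drop = FALSE]
  upper <- mat[pmin(lo + 2L, nOld), , drop = FALSE]
  # written as lower + w * (upper - lower) so constants are preserved exactly
  out <- lower + w * (upper - lower)
  dNew <- d[perm]
  dNew[1] <- nNew
  aperm(array(out, dNew), order(perm))
}

.resampleLinear <- function(volume, newDim) {
  for (ax in seq_along(newDim)) volume <- .resampleAxis(volume, ax, newDim[ax])
  volume
}

#' Degrade a volume to low resolution (and back to the HR grid)
#'
#' Image-domain degradation: the volume is resampled to a coarse grid by
#' linear interpolation (per-axis factors), then linearly resampled back
#' to the original grid to obtain the co-registered model input. Constant
#' volumes are preserved exactly. Presets: `"brain4x"` uses isotropic
#' factor 4 (0.8 mm -> 3.2 mm); `"prostate"` uses 3 per in-plane axis
#' (area factor 9) and 2 through-plane (0.66/1.5 mm -> ~2/3 mm).
#'
#' @param volume 3D numeric array.
#' @param factors Per-axis downsampling factors (>= 1), or use `preset`.
#' @param preset Optional `"brain4x"` or `"prostate"`.
#' @param spacing Optional voxel spacing (mm per axis) to propagate.
#' @return List with `lr` (coarse volume), `lrUp` (re-upsampled to the HR
#'   grid), `lrDim`, and `lrSpacing` (when `spacing` given).
#' @export
degradeVolume <- function(volume, factors = NULL,
                          preset = c("none", "brain4x", "prostate"),
                          spacing = NULL) {
  preset <- match.arg(preset)
  if (is.null(factors)) {
    factors <- switch(preset,
                      brain4x = c(4, 4, 4),
                      prostate = c(3, 3, 2),
                      stop("supply factors or a preset", call. = FALSE))
  }
  d <- dim(volume)
  stopIfNot(length(d) == 3L && length(factors) == 3L && all(factors >= 1),
            "volume must be 3D with three factors >= 1")
  lrDim <- as.integer(floor(d / factors))
  stopIfNot(all(lrDim >= 2), "downsampling factor leaves an axis < 2 samples")
  lr <- .resampleLinear(volume, lrDim)
  lrUp <- .resampleLinear(lr, d)
  out <- list(lr = lr, lrUp = lrUp, lrDim = lrDim)
  if (!is.null(spacing)) out$lrSpacing <- spacing * d / lrDim
  out
}

#' Select informative slices
#'
#' Removes the first and last `trim` slices along the slicing axis and any
#' slice whose background fraction (exactly-zero voxels after masking and
#' normalization) strictly exceeds `backgroundThreshold`.
#'
#' @param volume 3D array.
#' @param backgroundThreshold Background fraction above which a slice is
#'   dropped (default 0.95; a slice at exactly the threshold is kept).
#' @param trim Number of slices trimmed at each end (default 5).
#' @param axis Slicing axis (default 3).
#' @return Sorted integer vector of kept slice indices (1-based).
#' @export
selectSlices <- function(volume, backgroundThreshold = 0.95, trim = 5L,
                         axis = 3L) {
  n <- dim(volume)[axis]
  stopIfNot(n > 2L * trim, "volume too thin for the requested trim")
  cand <- (trim + 1L):(n - trim)
  keep <- vapply(cand, function(i) {
    sl <- switch(axis,
                 volume[i, , ], volume[, i, ], volume[, , i])
    mean(sl == 0) <= backgroundThreshold
  }, logical(1))
  cand[keep]
}

#' Read / write a NIfTI-1 volume
#'
#' Thin wrappers over RNifti preserving the data array, voxel spacing and
#' orientation affine. The slicing axis is the third array axis.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param volume Numeric array to write.
#' @param spacing Voxel spacing in mm per axis.
#' @return `readVolume`: list with `data` (array) and `meta` (list with
#'   `shape`, `spacing`, `sourceId`).
#' @export
readVolume <- function(path) {
  stopIfNot(file.exists(path), paste("file not found:", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("not a readable NIfTI file: ", path, call. = FALSE))
  arr <- as.array(img)
  pd <- RNifti::pixdim(img)
  list(data = arr,
       meta = list(shape = dim(arr), spacing = pd[seq_along(dim(arr))],
                   sourceId = basename(path)))
}

#' @rdname readVolume
#' @export
writeVolume <- function(path, volume, spacing = rep(1, length(dim(volume)))) {
  attr(volume, "pixdim") <- spacing
  RNifti::writeNifti(RNifti::asNifti(volume, datatype = "double"), path)
  invisible(path)
}

#' Export a single slice as PNG
#'
#' Writes a 2D slice (values clipped to `[0, 1]`) as an 8-bit grayscale
#' PNG, e.g. for quick visual inspection of LR/SR/HR triplets.
#'
#' @param slice Numeric matrix.
#' @param path Destination `.png` path.
#' @export
writeSlicePNG <- function(slice, path) {
  stopIfNot(requireNamespace("png", quietly = TRUE),
            "the 'png' package is required for PNG export")
  png::writePNG(pmin(pmax(slice, 0), 1), path)
  invisible(path)
}

#' Apply a binary mask
#'
#' Elementwise product of a volume with a (0/1) mask, e.g. a brain mask
#' used to remove extracranial signal. Mask generation itself is outside
#' the package's scope.
#'
#' @param volume,mask Equal-shaped arrays; `mask` binary.
#' @return Masked volume.
#' @export
applyMask <- function(volume, mask) {
  stopIfNot(identical(dim(volume), dim(mask)), "volume/mask shape mismatch")
  stopIfNot(all(mask %in% c(0, 1)), "mask must be binary")
  volume * mask
}
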