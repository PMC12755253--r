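# Paired image-quality metrics on 2D slices: PSNR, SSIM (Gaussian-window
# Wang-2004 variant), GMSD (Prewitt gradients) and a pluggable perceptual
# distance, plus batch aggregation.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(dataRange^2 / MSE)` in dB; `Inf` for identical images.
#'
#' @param x,y Equal-sized numeric matrices.
#' @param dataRange Intensity range of the data (1 after normalization).
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, dataRange = 1.0) {
  stopIfNot(identical(dim(x), dim(y)), "image shape mismatch")
  stopIfNot(dataRange > 0, "dataRange must be positive")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(dataRange^2 / mse)
}

.gaussKernel1d <- function(sigma = 1.5, radius = 5L) {
  x <- (-radius):radius
  k <- exp(-(x^2) / (2 * sigma^2))
  k / sum(k)
}

# separable filtering with replicate (nearest) edge padding
.sepFilter <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  ridx <- pmin(pmax(seq_len(H + 2L * r) - r, 1L), H)
  cidx <- pmin(pmax(seq_len(W + 2L * r) - r, 1L), W)
  pad <- img[ridx, cidx, drop = FALSE]
  tmp <- matrix(0, H, W + 2L * r)
  for (i in seq_along(k))
    tmp <- tmp + k[i] * pad[(i - 1L) + seq_len(H), , drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k))
    out <- out + k[i] * tmp[, (i - 1L) + seq_len(W), drop = FALSE]
  out
}

#' Structural similarity index
#'
#' Gaussian-window SSIM (11 x 11 window, sigma 1.5, K1 = 0.01, K2 = 0.03):
#' local means, variances and covariance are computed by Gaussian
#' filtering with replicate edge padding, the local SSIM map is evaluated,
#' the border of half a window is cropped, and the map mean is returned.
#'
#' @param x,y Equal-sized numeric matrices, at least 11 x 11.
#' @param sigma Gaussian window standard deviation.
#' @param K1,K2 Stabilization constants.
#' @param dataRange Intensity range of the data.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, y, sigma = 1.5, K1 = 0.01, K2 = 0.03, dataRange = 1.0) {
  stopIfNot(identical(dim(x), dim(y)), "image shape mismatch")
  r <- 5L
  stopIfNot(nrow(x) >= 2L * r + 1L && ncol(x) >= 2L * r + 1L,
            "image smaller than the 11x11 SSIM window")
  k <- .gaussKernel1d(sigma, r)
  C1 <- (K1 * dataRange)^2
  C2 <- (K2 * dataRange)^2
  mx <- .sepFilter(x, k)
  my <- .sepFilter(y, k)
  mxx <- .sepFilter(x * x, k)
  myy <- .sepFilter(y * y, k)
  mxy <- .sepFilter(x * y, k)
  vx <- mxx - mx * mx
  vy <- myy - my * my
  cxy <- mxy - mx * my
  S <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx * mx + my * my + C1) * (vx + vy + C2))
  core <- S[(r + 1L):(nrow(S) - r), (r + 1L):(ncol(S) - r), drop = FALSE]
  mean(core)
}

.prewitt <- function(img, horizontal = TRUE) {
  # 3x3 Prewitt, same-size correlation with replicate edge padding (so
  # constant images have exactly zero gradient and the gradient field is
  # invariant to global intensity shifts)
  H <- nrow(img); W <- ncol(img)
  pad <- img[pmin(pmax(0:(H + 1L), 1L), H), pmin(pmax(0:(W + 1L), 1L), W),
             drop = FALSE]
  out <- matrix(0, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    w <- if (horizontal) -dc / 3 else -dr / 3
    if (w != 0)
      out <- out + w * pad[(2L + dr):(H + 1L + dr), (2L + dc):(W + 1L + dc)]
  }
  out
}

#' Gradient magnitude similarity deviation
#'
#' Prewitt gradient magnitudes `m1`, `m2` of the two images; the gradient
#' magnitude similarity map `GMS = (2 m1 m2 + c) / (m1^2 + m2^2 + c)`; and
#' GMSD as the population standard deviation of that map. Lower is
#' better; 0 for images with identical gradients. The constant `c`
#' defaults to `170 / 255^2`, the original 8-bit constant rescaled to
#' `[0, 1]` intensities.
#'
#' @param x,y Equal-sized numeric matrices.
#' @param c Gradient-similarity stabilization constant.
#' @return Nonnegative scalar.
#' @export
gmsd <- function(x, y, c = 170 / 255^2) {
  stopIfNot(identical(dim(x), dim(y)), "image shape mismatch")
  m1 <- sqrt(.prewitt(x, TRUE)^2 + .prewitt(x, FALSE)^2)
  m2 <- sqrt(.prewitt(y, TRUE)^2 + .prewitt(y, FALSE)^2)
  gms <- (2 * m1 * m2 + c) / (m1^2 + m2^2 + c)
  sqrt(mean((gms - mean(gms))^2))
}

#' Perceptual image distance
#'
#' Distance under a pluggable perceptual backend. When a learned-feature
#' backend is available it can be passed as a function
#' `function(x, y) -> scalar` (grayscale inputs should be replicated to
#' three channels by the backend); otherwise the built-in gradient-domain
#' proxy ([gradientPerceptual()]) is used, with a one-time warning so
#' results are not mistaken for learned-feature distances.
#'
#' @param x,y Equal-sized numeric matrices.
#' @param backend `NULL` (proxy) or a backend function.
#' @return Nonnegative scalar, 0 for identical inputs.
#' @export
lpipsDistance <- function(x, y, backend = NULL) {
  stopIfNot(identical(dim(x), dim(y)), "image shape mismatch")
  if (is.null(backend)) {
    if (!isTRUE(getOption("MambaSR.proxyWarned"))) {
      warning("no learned perceptual backend supplied; ",
              "using the gradient-domain proxy", call. = FALSE)
      options(MambaSR.proxyWarned = TRUE)
    }
    return(gradientPerceptual(x, y)$value)
  }
  val <- backend(x, y)
  if (is.list(val)) val$value else val
}

#' Evaluate paired reconstructions
#'
#' Computes all four metrics for each (SR, HR) pair and aggregates a
#' mean +/- SD summary (sample standard deviation) per metric.
#'
#' @param cases List of pairs, each `list(sr = , hr = )` (optionally with
#'   a `caseId`).
#' @param method Method name recorded on every row.
#' @param lpipsBackend Optional backend for [lpipsDistance()].
#' @return List with `records` (one data.frame row per case:
#'   `case_id, method, psnr, ssim, gmsd, lpips`) and `summary`
#'   (mean/SD per metric, rounded views at 2 and 3 decimals).
#' @export
evaluatePairs <- function(cases, method = "model", lpipsBackend = NULL) {
  stopIfNot(length(cases) > 0, "no cases supplied")
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    data.frame(
      case_id = if (!is.null(cs$caseId)) cs$caseId else i,
      method = method,
      psnr = psnr(cs$sr, cs$hr),
      ssim = ssim(cs$sr, cs$hr),
      gmsd = gmsd(cs$sr, cs$hr),
      lpips = lpipsDistance(cs$sr, cs$hr, lpipsBackend),
      stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  metrics <- c("psnr", "ssim", "gmsd", "lpips")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(records[[m]]), numeric(1)),
    sd = vapply(metrics, function(m)
      if (nrow(records) > 1) sd(records[[m]]) else 0, numeric(1)),
    row.names = NULL)
  summary$table2dp <- sprintf("%.2f ± %.2f", summary$mean, summary$sd)
  summary$text3dp <- sprintf("%.3f ± %.3f", summary$mean, summary$sd)
  list(records = records, summary = summary)
}
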