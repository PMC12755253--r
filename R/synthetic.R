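# Synthetic phantoms and reader-score tables.
#
# Phantoms are ellipsoid compositions (piecewise-smooth, sharp boundaries)
# with optional band-limited texture and Gaussian noise — a stand-in for
# anatomical slices sufficient to exercise edge restoration, not a claim of
# anatomical realism. Reader tables follow a latent-quality + reader-bias +
# noise model so the preference machinery can be validated against a known
# planted ordering.

#' Phantom specification
#'
#' @param height,width,depth Volume dimensions.
#' @param nEllipses Number of random intensity ellipsoids composed on top
#'   of a base ellipsoid.
#' @param textureAmplitude Weight of the band-limited cosine texture.
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed RNG seed; output is a pure function of the spec.
#' @return List of class `"PhantomSpec"`.
#' @export
phantomSpec <- function(height = 32L, width = 32L, depth = 20L,
                        nEllipses = 6L, textureAmplitude = 0.08,
                        noiseSd = 0.01, seed = 1L) {
  stopIfNot(height >= 1 && width >= 1 && depth >= 1,
            "dimensions must be positive")
  structure(list(height = as.integer(height), width = as.integer(width),
                 depth = as.integer(depth), nEllipses = as.integer(nEllipses),
                 textureAmplitude = textureAmplitude, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a phantom volume
#'
#' Composes a large base ellipsoid ("head") with `nEllipses` random
#' additive ellipsoids of varying intensity, axes and in-plane rotation,
#' adds band-limited cosine texture inside the support, optional Gaussian
#' noise, and clamps below at 0. Deterministic for a fixed spec.
#'
#' @param spec A [phantomSpec()].
#' @return List with `data` (H x W x depth array, values roughly in
#'   `[0, 1.2]` pre-normalization) and `meta` (shape, spacing, sourceId).
#' @export
generatePhantomVolume <- function(spec) {
  stopIfNot(inherits(spec, "PhantomSpec"), "spec must be a phantomSpec()")
  h <- spec$height; w <- spec$width; d <- spec$depth
  .withSeed(spec$seed, {
    xs <- if (w > 1) seq(-1, 1, length.out = w) else 0
    ys <- if (h > 1) seq(-1, 1, length.out = h) else 0
    zs <- if (d > 1) seq(-1, 1, length.out = d) else 0
    Y <- array(rep(ys, times = w * d), c(h, w, d))
    X <- array(rep(rep(xs, each = h), times = d), c(h, w, d))
    Z <- array(rep(zs, each = h * w), c(h, w, d))
    vol <- array(0, c(h, w, d))
    support <- array(FALSE, c(h, w, d))
    if (spec$nEllipses > 0) {
      base <- (X / 0.85)^2 + (Y / 0.9)^2 + (Z / 0.95)^2 <= 1
      vol[base] <- vol[base] + 0.5
      support <- base
      for (i in seq_len(spec$nEllipses)) {
        cx <- runif(1, -0.5, 0.5); cy <- runif(1, -0.5, 0.5)
        cz <- runif(1, -0.5, 0.5)
        ax <- runif(1, 0.12, 0.45); ay <- runif(1, 0.12, 0.45)
        az <- runif(1, 0.2, 0.6)
        th <- runif(1, 0, pi)
        amp <- sample(c(-1, 1), 1) * runif(1, 0.15, 0.45)
        Xr <- (X - cx) * cos(th) + (Y - cy) * sin(th)
        Yr <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
        inside <- (Xr / ax)^2 + (Yr / ay)^2 + ((Z - cz) / az)^2 <= 1
        vol[inside] <- vol[inside] + amp
      }
      if (spec$textureAmplitude > 0) {
        tex <- array(0, c(h, w, d))
        for (k in 1:4) {
          fx <- runif(1, 1, 4); fy <- runif(1, 1, 4); fz <- runif(1, 0.5, 2)
          ph <- runif(3, 0, 2 * pi)
          tex <- tex + cos(pi * fx * X + ph[1]) * cos(pi * fy * Y + ph[2]) *
            cos(pi * fz * Z + ph[3])
        }
        vol[support] <- vol[support] +
          spec$textureAmplitude * tex[support] / 4
      }
    }
    if (spec$noiseSd > 0)
      vol <- vol + array(rnorm(h * w * d, sd = spec$noiseSd), c(h, w, d))
    vol[vol < 0] <- 0
    list(data = vol,
         meta = list(shape = c(h, w, d), spacing = c(1, 1, 1),
                     sourceId = sprintf("phantom-seed%d", spec$seed)))
  })
}

#' Build a paired LR/HR slice dataset from a phantom
#'
#' Full preprocessing pipeline on a synthetic volume: percentile
#' normalization (1st/99th), degradation with the chosen preset
#' ([degradeVolume()]), slice selection (trim 5, background rule), and
#' emission of co-registered LR (re-upsampled) / HR slice pairs.
#'
#' @param spec A [phantomSpec()].
#' @param preset `"brain4x"` (isotropic factor 4) or `"prostate"`
#'   (3 x 3 in-plane, 2 through-plane).
#' @param trim,backgroundThreshold Slice-selection parameters.
#' @return List of slice samples: each `list(lr, hr, volumeId, sliceIndex,
#'   axis)` with both matrices in `[0, 1]` on the HR grid.
#' @export
makePairedDataset <- function(spec, preset = c("brain4x", "prostate"),
                              trim = 5L, backgroundThreshold = 0.95) {
  preset <- match.arg(preset)
  ph <- generatePhantomVolume(spec)
  norm <- percentileNormalize(ph$data)
  deg <- degradeVolume(norm, preset = preset)
  keep <- selectSlices(norm, backgroundThreshold = backgroundThreshold,
                       trim = trim)
  lapply(keep, function(i)
    list(lr = deg$lrUp[, , i], hr = norm[, , i],
         volumeId = ph$meta$sourceId, sliceIndex = i, axis = 3L))
}

#' Synthetic reader specification
#'
#' @param methods Character vector of method names.
#' @param nCases,nReaders Study size.
#' @param qualityMeans Named (or positional) per-method latent quality on
#'   the 1-5 scale.
#' @param readerBiasSd Reader-level additive bias SD.
#' @param noiseSd Instance-level noise SD.
#' @param seed RNG seed.
#' @return List of class `"SyntheticReaderSpec"`.
#' @export
syntheticReaderSpec <- function(methods, nCases = 25L, nReaders = 3L,
                                qualityMeans, readerBiasSd = 0.3,
                                noiseSd = 0.5, seed = 1L) {
  stopIfNot(length(methods) >= 1, "need at least one method")
  stopIfNot(length(qualityMeans) == length(methods),
            "one latent quality per method")
  structure(list(methods = methods, nCases = as.integer(nCases),
                 nReaders = as.integer(nReaders),
                 qualityMeans = setNames(qualityMeans, methods),
                 readerBiasSd = readerBiasSd, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "SyntheticReaderSpec")
}

#' Generate a synthetic Likert table
#'
#' `score(i, m) = round(clip(quality[m] + bias[reader] + noise, 1, 5))`;
#' deterministic per seed. Emits the long-format table expected by
#' [preferenceAnalysis()].
#'
#' @param spec A [syntheticReaderSpec()].
#' @return data.frame with columns `dataset, reader, case, method, score`.
#' @export
generateLikertTable <- function(spec) {
  stopIfNot(inherits(spec, "SyntheticReaderSpec"),
            "spec must be a syntheticReaderSpec()")
  .withSeed(spec$seed, {
    bias <- rnorm(spec$nReaders, sd = spec$readerBiasSd)
    rows <- expand.grid(reader = seq_len(spec$nReaders),
                        case = seq_len(spec$nCases),
                        method = spec$methods,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    raw <- spec$qualityMeans[rows$method] + bias[rows$reader] +
      if (spec$noiseSd > 0) rnorm(nrow(rows), sd = spec$noiseSd) else 0
    data.frame(dataset = "synthetic", reader = rows$reader, case = rows$case,
               method = rows$method,
               score = as.integer(round(pmin(pmax(raw, 1), 5))),
               stringsAsFactors = FALSE)
  })
}
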