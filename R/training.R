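# Composite loss, Adam training loop, and inference.

#' Loss configuration
#'
#' Composite objective `lambdaL1 * mean|pred - target| + Lp(pred, target)`.
#' The perceptual term `Lp` is pluggable; the built-in `"gradient"` backend
#' is a gradient-domain perceptual proxy (mean absolute difference of
#' forward-difference image gradients) that requires no pretrained
#' weights. A custom backend is a `function(pred, target)` returning
#' `list(value = <scalar>, grad = <matrix like pred>)`.
#'
#' @param lambdaL1 Weight on the L1 term (default 4).
#' @param usePerceptual Include the perceptual term (default `TRUE`).
#' @param perceptualBackend `"gradient"` or a backend function.
#' @return List of class `"LossConfig"`.
#' @export
lossConfig <- function(lambdaL1 = 4, usePerceptual = TRUE,
                       perceptualBackend = "gradient") {
  stopIfNot(lambdaL1 >= 0, "lambdaL1 must be >= 0")
  structure(list(lambdaL1 = lambdaL1, usePerceptual = isTRUE(usePerceptual),
                 perceptualBackend = perceptualBackend),
            class = "LossConfig")
}

#' Training configuration
#'
#' Defaults follow the training protocol: Adam with initial learning rate
#' `2e-4`, batch size 8, 30 epochs, no learning-rate schedule and no data
#' augmentation.
#'
#' @param learningRate,batchSize,epochs,seed Training hyperparameters.
#' @param beta1,beta2,eps Adam moment parameters.
#' @return List of class `"TrainConfig"`.
#' @export
trainConfig <- function(learningRate = 2e-4, batchSize = 8L, epochs = 30L,
                        seed = 1L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopIfNot(learningRate >= 0 && batchSize >= 1 && epochs >= 1,
            "training hyperparameters must be positive")
  structure(list(learningRate = learningRate, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "TrainConfig")
}

.fdGradX <- function(img) img[, -1, drop = FALSE] - img[, -ncol(img), drop = FALSE]
.fdGradY <- function(img) img[-1, , drop = FALSE] - img[-nrow(img), , drop = FALSE]

#' Gradient-domain perceptual proxy
#'
#' Mean absolute difference of forward-difference spatial gradients between
#' two images: zero iff the images differ by at most a global constant,
#' symmetric, and sensitive to edge blurring. Serves as the default
#' perceptual term when no pretrained feature backend is available.
#'
#' @param pred,target Equal-sized numeric matrices.
#' @return List with `value` (scalar) and `grad` (d value / d pred).
#' @export
gradientPerceptual <- function(pred, target) {
  dgx <- .fdGradX(pred) - .fdGradX(target)
  dgy <- .fdGradY(pred) - .fdGradY(target)
  ntot <- length(dgx) + length(dgy)
  value <- (sum(abs(dgx)) + sum(abs(dgy))) / ntot
  grad <- matrix(0, nrow(pred), ncol(pred))
  sx <- sign(dgx) / ntot
  grad[, -1] <- grad[, -1, drop = FALSE] + sx
  grad[, -ncol(pred)] <- grad[, -ncol(pred), drop = FALSE] - sx
  sy <- sign(dgy) / ntot
  grad[-1, ] <- grad[-1, , drop = FALSE] + sy
  grad[-nrow(pred), ] <- grad[-nrow(pred), , drop = FALSE] - sy
  list(value = value, grad = grad)
}

.resolveBackend <- function(cfg) {
  be <- cfg$perceptualBackend
  if (is.function(be)) return(be)
  if (identical(be, "gradient")) return(gradientPerceptual)
  stop("unknown perceptual backend: ", be, call. = FALSE)
}

.lossParts <- function(pred, target, cfg, withGrad = TRUE) {
  stopIfNot(identical(dim(pred), dim(target)), "pred/target shape mismatch")
  stopIfNot(all(is.finite(pred)) && all(is.finite(target)),
            "non-finite intensities in loss inputs")
  diff <- pred - target
  l1 <- mean(abs(diff))
  lp <- 0
  gradP <- NULL
  if (cfg$usePerceptual) {
    be <- .resolveBackend(cfg)
    bres <- be(pred, target)
    if (is.list(bres)) {
      lp <- bres$value
      gradP <- bres$grad
    } else {
      lp <- bres
      gradP <- matrix(0, nrow(pred), ncol(pred))
    }
  }
  out <- list(l1 = l1, lp = lp, value = cfg$lambdaL1 * l1 + lp)
  if (withGrad) {
    g <- cfg$lambdaL1 * sign(diff) / length(diff)
    if (!is.null(gradP)) g <- g + gradP
    out$grad <- g
  }
  out
}

#' Composite reconstruction loss
#'
#' `lambdaL1 * mean|pred - target| + Lp(pred, target)`; the perceptual
#' term is zero when disabled.
#'
#' @param pred,target Equal-sized numeric matrices (intensities finite).
#' @param cfg A [lossConfig()].
#' @return Scalar loss value.
#' @export
compositeLoss <- function(pred, target, cfg = lossConfig()) {
  .lossParts(pred, target, cfg, withGrad = FALSE)$value
}

#' Train a super-resolution model
#'
#' Deterministic Adam training at desk scale. Each step samples a batch of
#' LR/HR slice pairs, runs the batched forward/backward pass, and applies
#' one Adam update. With `steps = NULL` the loop runs
#' `epochs * ceiling(n / batchSize)` steps over seeded shuffles of the
#' dataset; an explicit `steps` overrides that (batches sampled with
#' replacement), which is the mode used for small smoke experiments.
#'
#' @param model An [SRModel-class].
#' @param dataset Non-empty list of slice pairs, each a list with `lr` and
#'   `hr` matrices of one common size (see [makePairedDataset()]).
#' @param trainCfg A [trainConfig()].
#' @param lossCfg A [lossConfig()].
#' @param steps Optional explicit number of optimization steps.
#' @param logFile Optional path for a JSON-lines training log.
#' @return List with `model` (trained [SRModel-class]) and `trace`
#'   (data.frame with per-step loss components).
#' @export
trainModel <- function(model, dataset, trainCfg = trainConfig(),
                       lossCfg = lossConfig(), steps = NULL, logFile = NULL) {
  stopIfNot(length(dataset) > 0, "dataset must be non-empty")
  cfg <- model@config
  dims <- dim(dataset[[1]]$hr)
  H <- dims[1]; W <- dims[2]
  n <- length(dataset)
  bs <- min(trainCfg$batchSize, n)
  nStepsEpoch <- ceiling(n / bs)
  totalSteps <- if (is.null(steps)) trainCfg$epochs * nStepsEpoch else steps
  set.seed(trainCfg$seed)

  params <- model@params
  vec <- .flattenParams(params)
  mAdam <- numeric(length(vec))
  vAdam <- numeric(length(vec))
  b1 <- trainCfg$beta1; b2 <- trainCfg$beta2
  ctxCache <- list()
  trStep <- integer(totalSteps); trEpoch <- integer(totalSteps)
  trLoss <- numeric(totalSteps); trL1 <- numeric(totalSteps)
  trLp <- numeric(totalSteps)
  log <- if (!is.null(logFile)) file(logFile, "w") else NULL
  on.exit(if (!is.null(log)) close(log), add = TRUE)

  perm <- integer(0)
  for (st in seq_len(totalSteps)) {
    if (is.null(steps)) {
      if (length(perm) < bs) perm <- sample.int(n)
      idx <- perm[seq_len(bs)]
      perm <- perm[-seq_len(bs)]
    } else {
      idx <- sample.int(n, bs, replace = n < bs)
    }
    B <- length(idx)
    key <- as.character(B)
    if (is.null(ctxCache[[key]])) ctxCache[[key]] <- .modelContext(cfg, H, W, B)
    ctx <- ctxCache[[key]]
    X0 <- .imagesToBatch(lapply(dataset[idx], `[[`, "lr"))
    fw <- .modelForward(params, cfg, X0, ctx, train = TRUE)
    preds <- .batchToImages(fw$y, H, W, B)
    dY <- matrix(0, 1L, ncol(X0))
    l1s <- lps <- numeric(B)
    for (b in seq_len(B)) {
      lp <- .lossParts(preds[[b]], dataset[[idx[b]]]$hr, lossCfg)
      l1s[b] <- lp$l1; lps[b] <- lp$lp
      dY[1L, (b - 1L) * H * W + seq_len(H * W)] <-
        as.vector(t(lp$grad)) / B
    }
    lossVal <- lossCfg$lambdaL1 * mean(l1s) + mean(lps)
    if (!is.finite(lossVal))
      stop(sprintf("non-finite loss at step %d; aborting", st), call. = FALSE)
    bw <- .modelBackward(dY, fw$cache, params, cfg, ctx)
    gvec <- .flattenParams(bw$gw)
    mAdam <- b1 * mAdam + (1 - b1) * gvec
    vAdam <- b2 * vAdam + (1 - b2) * gvec * gvec
    mhat <- mAdam / (1 - b1^st)
    vhat <- vAdam / (1 - b2^st)
    vec <- vec - trainCfg$learningRate * mhat / (sqrt(vhat) + trainCfg$eps)
    params <- .unflattenParams(vec, params)
    ep <- if (is.null(steps)) ((st - 1L) %/% nStepsEpoch) + 1L else 1L
    trStep[st] <- st; trEpoch[st] <- ep
    trLoss[st] <- lossVal; trL1[st] <- mean(l1s); trLp[st] <- mean(lps)
    if (!is.null(log))
      writeLines(jsonlite::toJSON(list(step = st, epoch = ep, loss = lossVal,
                                       l1 = mean(l1s), lp = mean(lps),
                                       seed = trainCfg$seed),
                                  auto_unbox = TRUE, digits = NA), log)
  }
  model@params <- params
  model@meta$trainedSteps <- totalSteps
  list(model = model,
       trace = data.frame(step = trStep, epoch = trEpoch, loss = trLoss,
                          l1 = trL1, lp = trLp))
}

#' Super-resolve one or more slices
#'
#' Runs the network on LR slices pre-resampled to the HR grid (see
#' [degradeVolume()]); output spatial shape equals input shape.
#'
#' @param model An [SRModel-class].
#' @param lr A numeric matrix (one slice) or a list of equally sized
#'   matrices.
#' @return A matrix, or a list of matrices matching the input order.
#' @export
predictSlice <- function(model, lr) {
  single <- is.matrix(lr)
  imgs <- if (single) list(lr) else lr
  stopIfNot(length(imgs) > 0 && all(vapply(imgs, function(x)
    all(is.finite(x)), logical(1))), "non-finite input slice")
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  ctx <- .modelContext(model@config, H, W, length(imgs))
  fw <- .modelForward(model@params, model@config, .imagesToBatch(imgs), ctx)
  out <- .batchToImages(fw$y, H, W, length(imgs))
  if (single) out[[1]] else out
}

#' @describeIn predictSlice `predict` method for fitted models.
#' @param object An [SRModel-class].
#' @param newdata LR slice matrix or list of matrices.
#' @param ... Ignored.
#' @export
setMethod("predict", "SRModel",
          function(object, newdata, ...) predictSlice(object, newdata))
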