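# Workflow entry points tying the modules together. Artifacts are laid out
# deterministically under the configured output directory:
#   out/phantoms/  out/checkpoints/  out/logs/  out/metrics/  out/stats/
# Every command writes a JSON sidecar with the config hash and seed.

.ensureDir <- function(...) {
  d <- file.path(...)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

.writeSidecar <- function(dir, cfg, command) {
  jsonlite::write_json(
    list(command = command, configHash = configHash(cfg), seed = cfg$seed,
         config = unclass(cfg)),
    file.path(dir, paste0(command, ".run.json")),
    auto_unbox = TRUE, digits = NA, null = "null")
}

.phantomSpecs <- function(cfg) {
  s <- cfg$synth
  lapply(seq_len(s$nVolumes), function(i)
    phantomSpec(height = s$height, width = s$width, depth = s$depth,
                nEllipses = s$nEllipses,
                textureAmplitude = s$textureAmplitude,
                noiseSd = s$noiseSd, seed = cfg$seed + i - 1L))
}

.datasetFromConfig <- function(cfg) {
  specs <- .phantomSpecs(cfg)
  do.call(c, lapply(specs, makePairedDataset,
                    preset = cfg$preprocess$preset,
                    trim = cfg$preprocess$trim,
                    backgroundThreshold = cfg$preprocess$backgroundThreshold))
}

.cmdSynth <- function(cfg, out) {
  pdir <- .ensureDir(out, "phantoms")
  specs <- .phantomSpecs(cfg)
  rows <- lapply(seq_along(specs), function(i) {
    ph <- generatePhantomVolume(specs[[i]])
    p <- file.path(pdir, sprintf("phantom_%03d.nii.gz", i))
    writeVolume(p, ph$data, ph$meta$spacing)
    data.frame(volume_id = ph$meta$sourceId, path = p,
               split = if (i < length(specs)) "train" else "test",
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), file.path(pdir, "manifest.csv"),
            row.names = FALSE)
  lik <- generateLikertTable(syntheticReaderSpec(
    methods = c("bicubic", "model"), qualityMeans = c(2.5, 4.2),
    seed = cfg$seed))
  write.csv(lik, file.path(pdir, "likert.csv"), row.names = FALSE)
  invisible(pdir)
}

.cmdTrain <- function(cfg, out, steps = NULL) {
  dataset <- .datasetFromConfig(cfg)
  model <- buildModel(.configFromList(cfg$model))
  tc <- do.call(trainConfig, cfg$train)
  lc <- do.call(lossConfig, cfg$loss)
  ldir <- .ensureDir(out, "logs")
  fit <- trainModel(model, dataset, tc, lc, steps = steps,
                    logFile = file.path(ldir, "train.jsonl"))
  cdir <- .ensureDir(out, "checkpoints")
  saveCheckpoint(fit$model, file.path(cdir, "model.rds"))
  write.csv(fit$trace, file.path(ldir, "trace.csv"), row.names = FALSE)
  invisible(fit$model)
}

.cmdInfer <- function(cfg, out, input, checkpoint = NULL) {
  if (is.null(checkpoint)) checkpoint <- file.path(out, "checkpoints",
                                                   "model.rds")
  model <- loadCheckpoint(checkpoint)
  vol <- readVolume(input)
  sr <- vol$data
  for (i in seq_len(dim(sr)[3])) sr[, , i] <- predictSlice(model, sr[, , i])
  dst <- file.path(.ensureDir(out, "sr"),
                   paste0("sr_", basename(input)))
  writeVolume(dst, sr, vol$meta$spacing)
  invisible(dst)
}

.cmdEvaluate <- function(cfg, out, checkpoint = NULL) {
  if (is.null(checkpoint)) checkpoint <- file.path(out, "checkpoints",
                                                   "model.rds")
  model <- loadCheckpoint(checkpoint)
  dataset <- .datasetFromConfig(cfg)
  srCases <- lapply(dataset, function(sm)
    list(sr = predictSlice(model, sm$lr), hr = sm$hr,
         caseId = paste0(sm$volumeId, ":", sm$sliceIndex)))
  lrCases <- lapply(dataset, function(sm)
    list(sr = sm$lr, hr = sm$hr,
         caseId = paste0(sm$volumeId, ":", sm$sliceIndex)))
  recs <- rbind(evaluatePairs(srCases, method = "model")$records,
                evaluatePairs(lrCases, method = "interp")$records)
  mdir <- .ensureDir(out, "metrics")
  write.csv(recs, file.path(mdir, "metrics.csv"), row.names = FALSE)
  invisible(recs)
}

.cmdCompare <- function(cfg, out, metricsFile = NULL) {
  if (is.null(metricsFile)) metricsFile <- file.path(out, "metrics",
                                                     "metrics.csv")
  stopIfNot(file.exists(metricsFile),
            paste("metrics file not found:", metricsFile))
  recs <- read.csv(metricsFile, stringsAsFactors = FALSE)
  sdir <- .ensureDir(out, "stats")
  rows <- list()
  for (metric in intersect(c("psnr", "ssim", "gmsd", "lpips"), names(recs))) {
    vals <- recs[[metric]][is.finite(recs[[metric]])]
    grp <- recs$method[is.finite(recs[[metric]])]
    groups <- split(vals, grp)
    if (length(groups) < 2) next
    kw <- kruskalWallis(groups)
    dh <- dunnHolm(groups, names(groups))
    dh$metric <- metric
    dh$kruskal_H <- kw$H
    dh$omnibus_p <- kw$p
    rows[[metric]] <- dh
  }
  tab <- do.call(rbind, rows)
  write.csv(tab, file.path(sdir, "group_comparison.csv"), row.names = FALSE)
  invisible(tab)
}

.cmdReaderStats <- function(cfg, out, likertFile = NULL) {
  if (is.null(likertFile)) likertFile <- file.path(out, "phantoms",
                                                   "likert.csv")
  tab <- readLikert(likertFile)
  res <- preferenceAnalysis(tab)
  sdir <- .ensureDir(out, "stats")
  write.csv(res$pairs, file.path(sdir, "pairwise_preference.csv"),
            row.names = FALSE)
  write.csv(res$descriptives, file.path(sdir, "likert_descriptives.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(res$matrix), file.path(sdir,
                                                 "preference_matrix.csv"))
  invisible(res)
}

#' Run a pipeline command
#'
#' Dispatches one workflow step with a deterministic artifact layout under
#' `cfg$paths$out`. Commands: `"synth"` (phantom volumes + manifest +
#' synthetic Likert table), `"train"`, `"infer"`, `"evaluate"` (model vs.
#' interpolation metrics on the synthetic dataset), `"compare"`
#' (Kruskal-Wallis + Dunn/Holm on a metrics CSV), `"reader-stats"`
#' (preference analysis of a Likert CSV). Missing inputs raise a
#' named-path error before any computation; reruns with the same config
#' and seed reproduce outputs.
#'
#' @param command One of the commands above.
#' @param cfg A [runConfig()].
#' @param ... Command-specific options: `steps` (train), `input`,
#'   `checkpoint` (infer/evaluate), `metricsFile` (compare), `likertFile`
#'   (reader-stats).
#' @return Command-specific artifact (invisibly).
#' @export
runPipeline <- function(command = c("synth", "train", "infer", "evaluate",
                                    "compare", "reader-stats"),
                        cfg = runConfig(), ...) {
  command <- match.arg(command)
  stopIfNot(inherits(cfg, "RunConfig"), "cfg must be a runConfig()")
  out <- .ensureDir(cfg$paths$out)
  .writeSidecar(out, cfg, command)
  switch(command,
         synth = .cmdSynth(cfg, out),
         train = .cmdTrain(cfg, out, ...),
         infer = .cmdInfer(cfg, out, ...),
         evaluate = .cmdEvaluate(cfg, out, ...),
         compare = .cmdCompare(cfg, out, ...),
         `reader-stats` = .cmdReaderStats(cfg, out, ...))
}
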