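# Run configuration: YAML (de)serialization with strict schema checking.

.runConfigSchema <- list(
  model = names(formals(modelConfig)),
  train = c("learningRate", "batchSize", "epochs", "seed", "beta1", "beta2",
            "eps"),
  loss = c("lambdaL1", "usePerceptual", "perceptualBackend"),
  preprocess = c("preset", "pLow", "pHigh", "trim", "backgroundThreshold"),
  synth = c("nVolumes", "height", "width", "depth", "nEllipses",
            "textureAmplitude", "noiseSd"),
  paths = c("data", "out", "checkpoint"),
  seed = NULL
)

#' Build a run configuration
#'
#' A run configuration bundles the model, training, loss, preprocessing and
#' synthetic-data settings with a global seed; it serializes losslessly to
#' YAML. `preset` may name any ablation configuration
#' (see [makeAblationConfig()]).
#'
#' @param model,train,loss,preprocess,synth,paths Named lists overriding
#'   defaults of the respective component.
#' @param preset Optional ablation preset applied before overrides.
#' @param seed Global seed.
#' @return List of class `"RunConfig"`.
#' @export
runConfig <- function(model = list(), train = list(), loss = list(),
                      preprocess = list(), synth = list(), paths = list(),
                      preset = NULL, seed = 1L) {
  base <- list(
    model = .cfgList(modelConfig()),
    train = unclass(trainConfig()),
    loss = unclass(lossConfig()),
    preprocess = list(preset = "brain4x", pLow = 1, pHigh = 99, trim = 5,
                      backgroundThreshold = 0.95),
    synth = list(nVolumes = 2, height = 32, width = 32, depth = 20,
                 nEllipses = 6, textureAmplitude = 0.08, noiseSd = 0.01),
    paths = list(data = ".", out = "out", checkpoint = NA_character_),
    seed = as.integer(seed)
  )
  if (!is.null(preset)) {
    ab <- makeAblationConfig(preset)
    base$model <- .cfgList(ab$config)
    base$loss <- unclass(ab$loss)
  }
  for (sec in c("model", "train", "loss", "preprocess", "synth", "paths")) {
    ov <- get(sec)
    .checkKeys(ov, .runConfigSchema[[sec]], sec)
    base[[sec]] <- modifyList(base[[sec]], ov)
  }
  structure(base, class = "RunConfig")
}

.checkKeys <- function(x, allowed, where) {
  if (is.null(x) || length(x) == 0) return(invisible(TRUE))
  bad <- setdiff(names(x), allowed)
  stopIfNot(length(bad) == 0,
            sprintf("unknown configuration key(s) in '%s': %s", where,
                    paste(bad, collapse = ", ")))
  invisible(TRUE)
}

#' Load / save a run configuration (YAML)
#'
#' `loadConfig` validates the schema and rejects unknown keys with a named
#' error; `saveConfig` writes YAML. Round-trips are lossless.
#'
#' @param path YAML file path.
#' @param cfg A [runConfig()].
#' @export
loadConfig <- function(path) {
  stopIfNot(file.exists(path), paste("config file not found:", path))
  raw <- yaml::read_yaml(path)
  .checkKeys(raw, c(names(.runConfigSchema), "preset"), "top level")
  do.call(runConfig, raw[!vapply(raw, is.null, logical(1))])
}

#' @rdname loadConfig
#' @export
saveConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Stable digest of a run configuration
#'
#' MD5 of the canonical YAML serialization; embedded in output sidecars so
#' artifacts from different runs cannot be silently mixed.
#'
#' @param cfg A [runConfig()].
#' @return Character MD5 string.
#' @export
configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  saveConfig(cfg, tmp)
  unname(tools::md5sum(tmp))
}
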