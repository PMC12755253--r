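# Shared fixtures and small helpers, all built in code.

# deterministic formula images used for frozen metric cross-checks
metricFixture <- function() {
  H <- 48L; W <- 48L
  i <- matrix(rep(1:H, W), H)
  j <- matrix(rep(1:W, each = H), H)
  x <- 0.5 + 0.25 * sin(i * 0.3) * cos(j * 0.2) + 0.1 * sin((i + j) * 0.13)
  y <- pmin(pmax(x + 0.05 * sin(i * 1.1) * cos(j * 0.9), 0), 1)
  list(x = pmin(pmax(x, 0), 1), y = y)
}

gmsdFixture <- function() {
  list(
    a = matrix(c(0, 1, 2, 3, 4,
                 1, 2, 3, 4, 5,
                 2, 3, 4, 5, 6,
                 3, 4, 5, 6, 7,
                 4, 5, 6, 7, 8), 5, byrow = TRUE) / 8,
    b = matrix(c(0, 1, 1, 3, 4,
                 1, 3, 3, 4, 5,
                 2, 3, 5, 5, 6,
                 3, 4, 5, 7, 7,
                 4, 5, 6, 7, 8), 5, byrow = TRUE) / 8)
}

# head parameters with an exactly fixed step size (softplus(b2) == delta)
fixedDeltaHead <- function(channels, stateSize, delta, ...) {
  ssmHeadParams(channels, stateSize,
                delta = list(W1 = matrix(0, 1L, channels), b1 = 0,
                             W2 = matrix(0, 1L, 1L), b2 = log(expm1(delta))),
                ...)
}

tinyModelConfig <- function(seed = 1L)
  modelConfig(stageRepeats = c(1L, 1L, 1L, 1L), embedDim = 16L,
              scanCount = 4L, heads = 4L, stateSize = 8L, seed = seed)

microModelConfig <- function(seed = 1L)
  modelConfig(stageRepeats = c(1L, 1L, 1L, 1L), embedDim = 8L,
              scanCount = 4L, heads = 4L, stateSize = 2L, seed = seed)
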