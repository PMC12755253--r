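# MambaSR

Lightweight selective state-space (Vision-Mamba) super-resolution for
single-channel MRI slices, with the full evaluation stack around it:
preprocessing, image-quality metrics, nonparametric group statistics, and
Likert reader-study preference analysis. Everything runs on one CPU, and a
synthetic phantom module makes the whole pipeline reproducible without any
data download.

## Who this is for

Researchers who want a small, fully inspectable MRI super-resolution
baseline — under one million parameters, trained with an ordinary Adam
loop — together with the statistical machinery used to compare SR methods
(PSNR/SSIM/GMSD/perceptual distance, Kruskal–Wallis with Dunn/Holm post
hoc, pairwise reader preferences with exact binomial tests).

## The model

Low-resolution slices are resampled to the high-resolution grid by linear
interpolation; the network learns the residual detail on that grid. The
architecture is a four-stage MambaFormer (stages repeated 4, 6, 6, 7
times) of pre-norm residual blocks

```
z'  = z  + MHSSM(LN(z))
z'' = z' + ChannelMLP(LN(z'))
```

where the multi-head selective state-space module (MHSSM) serializes the
token grid along a hybrid set of scan orders — horizontal, vertical and
both diagonal traversals, forward and reverse — and runs one selective
scan per path:

```
h_t = exp(Δ_t A) h_{t-1} + Φ(Δ_t, A) B_t u_t,      y_t = C_t h_t + D u_t
A = diag(-exp(a)),   Φ(Δ, A) = (exp(ΔA) - I) A⁻¹,   Δ_t = softplus(MLP(u_t))
```

Diagonal scanning keeps diagonally adjacent pixels adjacent in the
sequence, mitigating the "pixel forgetting" of raster scans. The channel
MLP is a gated pointwise layer (expand by α = 2, split, multiply, project).
Training minimizes `4·L1 + perceptual` with Adam at 2e-4. The forward and
backward passes are implemented in the package itself (R + small C++
kernels) and are verified against finite differences and a literal
per-step recurrence oracle.

See `vignettes/mamba-sr-methods.Rmd` for the full account of the model,
its assumptions, and every numerical choice.

## Worked example

```r
library(MambaSR)

## the default configuration stays under the 0.9M parameter budget
model <- buildModel(modelConfig())
countParameters(model)
#> [1] 880441

## reader-study statistics from head-to-head win/loss counts
round(preferenceRate(28, 5), 3)          # preference rate, ties excluded
#> [1] 0.848
signif(exactBinomialTwoSided(28, 33), 2) # two-sided exact binomial test
#> [1] 6.6e-05

## end-to-end on synthetic phantoms: degrade, train a tiny model, compare
train <- makePairedDataset(phantomSpec(height = 24, width = 24, seed = 11),
                           "brain4x")[1:8]
test  <- makePairedDataset(phantomSpec(height = 24, width = 24, seed = 501),
                           "brain4x")
tiny <- buildModel(modelConfig(stageRepeats = c(1, 1, 1, 1), embedDim = 16,
                               scanCount = 4, heads = 4, seed = 1))
fit <- trainModel(tiny, train, trainConfig(seed = 1), lossConfig(),
                  steps = 500)
median(sapply(test, function(p) psnr(p$lr, p$hr)))                  # baseline
#> [1] 16.23
median(sapply(test, function(p) psnr(predictSlice(fit$model, p$lr), p$hr)))
#> [1] 16.79
```

The trained model beats the linear-interpolation baseline by about half a
decibel on held-out phantoms after 500 steps (a few minutes on one CPU);
the numbers above are what the code prints at these seeds.

A thin command-line wrapper (`inst/cli/mambasr.R`) exposes the same
workflows (`synth`, `train`, `infer`, `evaluate`, `compare`,
`reader-stats`) over YAML run configurations; see `?runPipeline`.

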