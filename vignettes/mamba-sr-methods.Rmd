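---
title: "Selective state-space super-resolution for MRI slices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective state-space super-resolution for MRI slices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MambaSR)
```

MambaSR implements a lightweight Vision-Mamba network for single-channel
MRI super-resolution together with the preprocessing, image-quality and
reader-study machinery needed to evaluate it. This vignette explains the
model, its assumptions, the tunable parameters, the numerical choices, and
what the synthetic experiments shipped with the package do and do not
demonstrate.

## The problem

MRI resolution trades off against scan time: coarser voxels are faster to
acquire but blur anatomy. Super-resolution (SR) learns the mapping from a
low-resolution (LR) slice back to its high-resolution (HR) counterpart.
The package treats SR slice-wise in 2D: LR slices are first resampled to
the HR grid by linear interpolation, and the network learns the residual
detail on that common grid. The network is therefore grid-preserving; the
`upsampleFactor` in a `ModelConfig` is provenance metadata, not an
in-network upsampler.

## Scan orders and pixel forgetting

A state-space scan consumes a 1D sequence, so a 2D token grid must be
serialized. A plain raster scan places a pixel's diagonal neighbours up to
a full row apart in the sequence — after serialization, spatially adjacent
pixels no longer interact ("pixel forgetting"). Diagonal traversals keep
all cells of one anti-diagonal consecutive, so diagonal neighbours stay at
sequence distance 1.

`buildScanOrder()` constructs five canonical traversals (`horizontal`,
`vertical`, `antidiagonal`, `maindiagonal`, `zigzag`), each forward or
reversed, as explicit permutations with their inverses.
`buildScanSet()` assembles the hybrid multi-path set: with
`scanCount = 8`, four kinds crossed with both directions; with
`scanCount = 4`, forward directions only, so every scan family stays
represented. Two conventions are deliberate choices (the traversal inside
an anti-diagonal is by increasing row; zigzag alternates JPEG-style), made
for canonicality and testability; any fixed convention would serve the
model equally.

## The selective state-space recurrence

Each scan head runs a diagonal continuous-time linear system, discretized
per token by a zero-order hold:

$$\bar A_t = e^{\Delta_t A}, \qquad
  \Phi(\Delta_t, A) = (e^{\Delta_t A} - I)\,A^{-1},$$
$$h_t = \bar A_t\, h_{t-1} + \Phi(\Delta_t, A)\, B_t\, u_t, \qquad
  y_t = C_t\, h_t + D\, u_t,$$

with $A = \mathrm{diag}(-e^{a})$ so the system is stable for any real
parameter vector $a$: every $\bar A_t$ entry lies strictly in $(0, 1)$ for
$\Delta_t > 0$. The step size $\Delta_t$ is predicted per token per head by
a two-layer channel MLP with a softplus reparameterization, which makes
the recurrence *selective*: informative tokens can take large steps
(fast state update) while background tokens decay the state slowly.

Two points the recurrence leaves open were resolved as follows and are
switchable in `modelConfig()`:

* **Input-dependent B and C** (`selectiveBC = TRUE`, default): $B_t$ and
  $C_t$ are linear projections of the token, following the selective-scan
  convention; the static alternative (fixed vectors per head) is retained
  for analysis because several closed-form tests are only expressible
  there.
* **Head count** is tied to the number of scan paths (one head per
  traversal), the natural reading of "m parallel recurrent scans".

Each head processes the full channel width; head outputs are concatenated
(m·D channels), layer-normalized, multiplied by a SiLU gate computed from
the module input (`gated = TRUE` by default), and projected back to D.
This layout is what makes the head-permutation symmetry hold: permuting
heads together with their assigned orders only permutes channel blocks
before the projection.

State size `stateSize` defaults to N = 8 per head. The state is zeroed at
the start of every slice; no information is carried across slices.

## Architecture

The network is a four-stage MambaFormer with pre-norm residual blocks:

$$z' = z + \mathrm{MHSSM}(\mathrm{LN}(z)), \qquad
  z'' = z' + \mathrm{ChannelMLP}(\mathrm{LN}(z')).$$

The MHSSM module is: 1×1 projection → depthwise 3×3 convolution → SiLU →
multi-head selective scan → merge (LN, gate) → 1×1 projection. The channel
MLP expands by `alpha` (default 2) with a 1×1 convolution, splits the
expanded channels in half, multiplies the halves elementwise (a
multiplicative gate in place of a pointwise nonlinearity), and projects
back. `alpha * embedDim` must be even so the split is exact.

Around the blocks: a 3×3 convolution embeds the image into `embedDim`
channels; a 3×3 body convolution with a global feature residual from the
embedding output stabilizes training; a final 3×3 convolution maps back to
one channel, added to the input image (global image residual).

The default `stageRepeats = c(4, 6, 6, 7)` gives 23 blocks. The default
width is *derived*, not free: `embedDim = 46` is the largest even width
whose full configuration stays below the 0.9-million-parameter budget
(`countParameters(buildModel(modelConfig()))` = 880,441). Residual-branch
output layers (block output projections, body and tail convolutions) are
zero-initialized, so a freshly built model is exactly the identity map on
images — training starts from the interpolation baseline rather than from
noise. `estimateFlops()` reports analytic multiply-accumulate counts;
because the counting convention (MACs, all layers, chosen input size) is
part of any such figure, cross-study FLOP comparisons should use the
values each study reports, and the package makes no claim of reproducing a
specific reported GFLOP figure.

```{r}
cfg <- modelConfig()
countParameters(buildModel(cfg))
estimateFlops(cfg, c(288, 288)) / 1e9  # GMACs at a 288 x 288 slice
```

`makeAblationConfig()` exposes the named ablation presets
(`baseline`, `blocks_light`, `block_heavy`, `scan4`, `zigzag_scan`,
`alpha1`, `l1_only`) as ready configurations.

## Training

The objective is
$$L = \lambda\,\|\hat x - x\|_1 + \ell_p(\hat x, x), \qquad \lambda = 4,$$
mean-reduced over pixels and batch. The perceptual term $\ell_p$ is
pluggable. The built-in default is a gradient-domain proxy — the mean
absolute difference of forward-difference image gradients — chosen so the
package trains and tests without downloading pretrained feature networks;
it is zero iff the two images differ by a constant, symmetric, and
sensitive to edge blurring, which is the aspect of perceptual quality SR
cares about most. A learned-feature backend can be supplied as a function
and is used verbatim; grayscale replication to three channels is the
backend's responsibility.

Optimization is Adam (β = 0.9/0.999) at a fixed learning rate of 2×10⁻⁴,
batch size 8, and no learning-rate schedule or data augmentation. The
entire forward/backward pass is implemented in the package (R with small
C++ kernels for the scan recurrence, layer norm and convolution
gather/scatter); its correctness is enforced by a finite-difference
gradient check over randomly sampled coordinates of every parameter
tensor. Training is bit-reproducible under a fixed seed on one machine:
batch shuffling is the only source of randomness and is seeded.

Calibration of the shipped smoke experiments (package choices, measured
once with the package's own training loop and then frozen):

* *Overfit smoke*: one 32×32 phantom pair, 600 Adam steps at the default
  learning rate cuts the L1 error below 20% of its initial value. At this
  learning rate the 0.2 ratio is reached at roughly 500 steps (200 steps
  only reaches ≈0.39); the smoke runs 600 for margin.
* *Generalization gate*: a tiny model (stages `[1,1,1,1]`, width 16, 4
  scan paths) trained 500 steps on 8 phantom pairs (24×24 slices) is
  compared against the linear-interpolation baseline by median PSNR on
  held-out phantoms from fresh seeds, and must win for the majority of 3
  seeds. The 24×24 size keeps the three runs within a ~10-minute
  single-CPU budget; the margin is typically 0.5–3 dB, and an occasional
  losing seed is expected — the gate is stochastic by design.

## Preprocessing

`percentileNormalize()` maps a volume to [0, 1] by its 1st/99th
percentiles (linear interpolation between order statistics), clipping
outliers; with a mask, percentiles are computed over foreground voxels
only (the unmasked default matches the common per-volume convention; which
of the two a study used is often unstated, so both are provided).
"Background" is defined as exactly-zero voxels after masking and
normalization.

`degradeVolume()` degrades in the image domain by separable,
center-aligned linear interpolation to the coarse grid and resamples back
to the HR grid for the co-registered model input; constants are preserved
exactly (the interpolation is written as `lower + w * (upper - lower)`).
The `brain4x` preset is isotropic factor 4 (0.8 mm → 3.2 mm); the
`prostate` preset is 3 per in-plane axis — the reading of "factor 9
in-plane" as an area factor, the only one consistent with the printed
0.66 mm → ~2 mm spacing change — and 2 through-plane (1.5 mm → 3 mm).

`selectSlices()` removes the first and last five slices and any slice with
strictly more than 95% background. Image-domain interpolation is a
simplified degradation model: it does not simulate k-space truncation,
partial-volume effects, or sequence-specific noise.

## Image-quality metrics

* **PSNR**: $10\log_{10}(R^2/\mathrm{MSE})$ with the data range fixed at
  1.0 after normalization; identical images report `Inf`.
* **SSIM**: the Gaussian-window variant (11×11 window, σ = 1.5,
  K₁ = 0.01, K₂ = 0.03), local statistics by Gaussian filtering with
  replicate edge padding, a half-window border crop, and the map mean.
  The implementation agrees with an independent reference implementation
  to 10⁻⁶ on frozen fixtures.
* **GMSD**: Prewitt gradient magnitudes, the gradient-magnitude-similarity
  map $(2m_1m_2 + c)/(m_1^2 + m_2^2 + c)$, and its population standard
  deviation. The constant is the original 8-bit value rescaled for [0, 1]
  inputs (c = 170/255²). The Prewitt filters use replicate edge padding so
  that constant images have exactly zero gradient and the GMS map is
  invariant to global intensity shifts — with zero padding neither holds
  at the border.
* **Perceptual distance**: a pluggable backend with the gradient-domain
  proxy as fallback (with a one-time warning, so proxy values are never
  silently mistaken for learned-feature distances).

## Statistical machinery

Group comparison over per-case metric values uses the tie-corrected
Kruskal–Wallis H with a χ² reference on k−1 degrees of freedom, followed
by Dunn's pairwise z tests (large-sample normal approximation with tie
correction) and Holm's step-down adjustment. These are implemented from
their rank definitions and cross-checked in the test suite against the
base-R reference implementations on random instances to 10⁻⁸.

The reader-study module implements the Likert winner rule (higher score
wins, equal is a tie), the pairwise preference rate
$\pi_{a>b} = W_a/(W_a + W_b)$ with ties excluded, a two-sided exact
binomial test of $\pi = 0.5$ by tail doubling
($p = \min(1, 2P(X \ge \max(k, n-k)))$, which coincides with the
minimum-likelihood two-sided test at p₀ = 0.5), per-method overall rates,
descriptives (mean, sample SD, median, interpolated-quartile IQR), and
the full preference matrix with a 50% diagonal. All-tie pairs have an
undefined preference rate and are flagged rather than imputed.

## Synthetic data: what it shows and what it does not

`generatePhantomVolume()` composes a base ellipsoid with random additive
ellipsoids (random centres, axes, in-plane rotation, signed intensities),
band-limited cosine texture inside the support, and optional Gaussian
noise; every generator is a pure function of its spec (seed included), and
the caller's RNG stream is left untouched. `makePairedDataset()` runs the
full preprocessing pipeline on a phantom and emits co-registered LR/HR
slice pairs. `generateLikertTable()` draws scores from a latent-quality +
reader-bias + noise model, rounded and clipped to 1–5, so preference
machinery can be validated against a planted ordering.

These phantoms exercise exactly what the SR model must do — restore sharp
boundaries and band-limited texture removed by linear-interpolation
degradation — and what the statistics must detect. They do *not* emulate
MRI contrast mechanisms, coil or bias fields, anatomical shape statistics,
or realistic noise spectra. Passing the shipped experiments demonstrates
that the implementation is correct and trainable, not that the
architecture reaches any particular quality on clinical data.

## Numerical choices

* $\Phi$ is computed elementwise for the diagonal state matrix, with a
  two-term Taylor fallback $\Phi \approx \Delta(1 + \Delta A/2)$ when
  $|\Delta A| < 10^{-6}$ to avoid catastrophic cancellation; the backward
  pass differentiates the same branch so gradients stay consistent.
* Layer norm uses ε = 10⁻⁶ over channels, per token.
* The vectorized scan kernel is required by the test suite to match a
  literal per-step scalar loop to 10⁻¹⁰ on 200 randomized instances.
* Checkpoints round-trip bit-exactly (RDS tensor archive + JSON config
  sidecar).
* Degenerate inputs fail loudly: constant volumes in normalization,
  all-tie pairs in preference rates, identical values in rank tests
  (H reported as 0 with a degeneracy flag).

## Problem sizes in the shipped experiments

All experiments run on one CPU: phantom volumes of 32×32×20 (24×24×20 for
the generalization gate), models from a few thousand (test "micro"
configurations) to 0.88 M parameters (default), training runs of 3–500
steps. These sizes are the package's choices for its own test suite;
the same code paths scale to full slices by changing the configuration.

## Known limitations

* 2D slice-wise processing; no volumetric coherence across slices.
* The degradation model is image-domain linear interpolation only.
* The default perceptual term is a gradient-domain proxy, not a
  learned-feature distance; supply a backend for LPIPS-style evaluation.
* Training is single-device, full-precision, and deliberately small-scale;
  there is no learning-rate schedule, augmentation, or distributed mode.
* FLOP accounting is analytic and convention-dependent; use it for
  relative comparisons between configurations of this package.
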