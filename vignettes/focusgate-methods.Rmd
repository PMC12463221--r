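---
title: "FocusGate-Net: model, training recipe and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FocusGate-Net: model, training recipe and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`focusgate` implements FocusGate-Net, a U-shaped encoder–decoder for
binary segmentation of dermoscopy-like images that combines three
mechanisms on top of a plain convolutional backbone:

* **Shifted Token MLP (ST-MLP).** After each encoder convolution the
  feature map `z` is refined as

  `z' = MLP_h(Shift_h(z)) + MLP_w(Shift_w(z)) + z`

  where `Shift_h` / `Shift_w` translate contiguous channel groups by a
  few pixels along height and width (zero-filled, no wrap-around) and
  each MLP is a position-shared two-layer perceptron over channels
  (`C -> 4C -> C`, ReLU in between, implemented as 1×1 projections).
  The shifts give each pixel access to its displaced neighbours before
  channel mixing, a cheap surrogate for spatial attention.

* **CBAM.** Channel attention `M_c = σ(MLP(avgpool F) + MLP(maxpool F))`
  (shared bottleneck MLP, reduction `r`) followed by spatial attention
  `M_s = σ(Conv7×7[avgpool_c; maxpool_c])` applied **sequentially**:
  the spatial map is computed on the channel-refined tensor,
  `F' = (F ⊙ M_c) ⊙ M_s(F ⊙ M_c)`.

* **Attention Gates (AG).** Each skip connection is filtered by
  `α = σ(ψ(ReLU(φ_x(x) + φ_g(g))))`, where `x` is the encoder feature,
  `g` the upsampled decoder feature of the same stage, `φ_x, φ_g` are
  1×1 projections to `C_x/2` intermediate channels and `ψ` a 1×1
  convolution with batch norm to one channel. The gated skip `α ⊙ x`
  is concatenated with the upsampled decoder feature.

The encoder has five stages with widths `[64, 128, 256, 512, 1024]`
(stage 1 preserves resolution, stages 2–5 are stride-2, i.e. scales
1/1 … 1/16); the decoder mirrors it with four transposed-convolution
stages of widths `[512, 256, 128, 64]`, each followed by two 3×3
conv+BN+ReLU refinements; a 1×1 convolution with sigmoid emits the
probability map. Training minimises the compound loss

`L = λ1·L_Dice + λ2·L_BCE`, `λ1 = λ2 = 0.5`,

with the soft-Dice overlap term and pixel-wise binary cross-entropy,
both stabilised by `ε = 1e-5`. The stabiliser sits *inside* the BCE
logarithms, so a perfect prediction scores ≈ `-ε` rather than 0; this
parameterisation is kept deliberately and documented in
`?bce_loss`.

## Native forward/backward passes

All layers — convolutions (im2col + GEMM), transposed convolutions,
batch norm, pooling, token shifts, the attention modules — are
implemented directly on BLAS-backed matrix operations, together with
their analytic backward passes and an Adam optimiser. This keeps the
whole computation inspectable: the test suite checks every block
against straight-line scalar re-implementations of its defining
formula (tolerance 1e-5 on small inputs) and every backward pass
against central finite differences (relative error ~1e-9). A
consequence is CPU-scale throughput: the package targets method
verification and small-data experiments, not GPU-scale training.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `encoder_channels` | `[64,128,256,512,1024]` | stage widths; the V2 preset uses `[16,32,64,128,256]` |
| `hidden_ratio` | 4 | ST-MLP hidden width multiplier |
| `cbam_reduction` | 16 | channel-attention bottleneck (floored at 1 channel) |
| shift grouping | 5 groups, offsets −2…+2 | token shift; remainder channels join the last group |
| `lr0`, `lr_min` | 1e-4, 1e-6 | peak and floor of the cosine schedule |
| `warmup_epochs` | 5 | linear ramp to `lr0` |
| `max_epochs`, `patience` | 30, 5 | budget and early stopping on validation Dice |
| `batch_size` | 8 (4 for the full-width variant) | minibatch size |
| `weight_decay` | 1e-4 | L2 added to Adam gradients |
| threshold | 0.5 | probability binarisation; ties map to foreground |

Weight initialisation: He for convolution kernels, Xavier for the
MLP-style 1×1 projections, identity for batch norm (γ=1, β=0, zeroed
running mean, unit running variance).

### Design choices where the design was open

* **Shift scheme.** The shift amounts and grouping are not pinned down
  by the architecture description; we partition channels into five
  contiguous near-equal groups with offsets {−2,−1,0,+1,+2}, zero-fill
  and never wrap — the convention of the shifted-MLP literature this
  block descends from. On feature maps smaller than the offset (deep
  stages of very small inputs) offsets are clamped to `extent − 1`,
  preserving sign.
* **ST-MLP form.** Two textual variants of the block circulate (a
  parallel two-branch form and a serial `MLP2(S(MLP1(F))) + F` form);
  the parallel form with per-axis branches is implemented as canonical.
  A decoder-side multiplicative re-application of attention that
  appears in one prose description is not implemented.
* **AG ReLU.** The gate applies ReLU between the addition and `ψ`
  (the gate diagram and the original attention-gate design both have
  it, even where the compact formula omits it).
* **CBAM reduction.** `r = 16`, the module's original default, with
  `max(1, C/r)` bottleneck width.
* **V7 vs V4.** The ablation grid nominally distinguishes "no AG"
  (V4) from "CBAM only" (V7); with ST-MLP kept on in both, the two
  configurations coincide. Both ids are provided for completeness and
  produce identical architectures at equal widths.
* **Warm-up shape.** Linear ramp `lr0·(e+1)/warmup` — the simplest
  continuous ramp reaching `lr0` exactly at the stated boundary; the
  scheduler steps per epoch.
* **Early-stopping improvement** means a strict increase of validation
  Dice by more than 1e-6.
* **Macro vs micro.** Whether reported metrics are per-image means or
  pooled-pixel ratios is ambiguous in common usage; `evaluate_model()`
  computes both and reports macro (per-image mean ± sd) as the default.
* **Degenerate metrics.** If both masks are empty, overlap metrics are
  defined as 1 (correctly empty prediction); a one-sidedly empty
  denominator yields 0. Thresholding maps ties (`p = 0.5`) to
  foreground, making `binarize()` total and idempotent.
* **Parameter accounting.** With `hidden_ratio = 4`, the stage-5
  ST-MLP alone contributes `16·C²` weights (≈16.8M at `C = 1024`), so
  the full default model has ≈41M parameters. Published parameter
  totals for architectures of this family are often inconsistent with
  their stated widths; the package therefore treats parameter counts
  as derived quantities (`count_parameters()`) and exposes
  `hidden_ratio` in the configuration rather than targeting any
  particular printed total.

## The synthetic data generator

`generate_sample()` emulates the gross structure of dermoscopic lesion
photographs so the full pipeline can run with no downloads:

* a single compact lesion whose outline is a low-order
  Fourier-perturbed oval (8 harmonics, amplitude ∝
  `boundary_irregularity / k`), placed near the image centre;
* an **area fraction drawn uniformly from 1%–75%** of the image and
  matched by construction: the outline is scaled through the empirical
  quantile of the normalised radius field, so the realised fraction
  equals the draw up to pixel discreteness;
* a darker, redder lesion over a textured skin-toned background at a
  contrast drawn from `contrast_range`, soft lesion edge (Gaussian
  blur of the mask at σ = 1.5), Gaussian acquisition noise;
* optional artifacts drawn over the image only: hair-like dark
  quadratic strokes and specular bright spots.

What it does **not** emulate: diagnostic-category appearance
differences, ruler markings and ink annotations, vignetting, colour
calibration drift between acquisition devices, multiple lesions.
Passing tests on this generator therefore demonstrates that the
implementation learns and evaluates correctly — not that the
architecture reaches any particular accuracy on real dermoscopy
benchmarks, which require the original datasets and GPU-scale
training and are out of scope here.

Augmentation applies geometric transforms (flips, ±30° rotation, ±20%
scaling, elastic deformation with α=1, σ=50) with identical parameters
to image and mask — masks resampled nearest-neighbour so labels stay
binary, images bilinearly with border replication — and photometric
transforms (brightness ±10%, contrast ±20%, gamma 0.8–1.2), Gaussian
noise (variance 0.01) and cutout (≤32×32) to the image only. Zeroing
rectangles out of the *mask* would corrupt the ground truth, so
"applied consistently to both" is interpreted as the spatial-alignment
requirement; this deliberate reading is documented in
`?augmentation_policy`. Validation and test pipelines apply
normalisation only.

Normalisation itself is two-stage: PNG decoding scales to [0,1], then
channels are standardised with mean/std computed from the *training*
split (population variance, so statistics are invariant under split
duplication; std floored at 1e-6). Cross-dataset protocols reuse one
split's statistics on another dataset via `stats_to_yaml()` /
`stats_from_yaml()`.

## Numerical choices

* Batch norm: ε = 1e-5, running-statistic momentum 0.1 (biased batch
  variance for normalisation, unbiased in the running estimate);
  evaluation mode uses running statistics, so early-training
  validation scores lag until the estimates converge.
* Max-pooling backward routes gradient to the first arg-max on ties.
* Dice loss is computed per image and averaged over the batch; BCE is
  averaged over all pixels.
* Grad-CAM's scalar target is the sum of predicted foreground
  probabilities (the simplest faithful reduction of a segmentation
  output); heatmaps are ReLU'd, max-normalised (identically zero when
  nothing activates, avoiding division blow-up) and bilinearly
  upsampled. The default target layer `"decoder.3.conv"` resolves to
  the last decoder convolution through a stable dotted-path registry.
* The inference timer runs two warm-up passes and reports the mean of
  10 timed single-image passes; wall-clock numbers are
  hardware-dependent context, never acceptance quantities.

## Problem sizes used in the tests

The suite verifies blocks on ≤4×4×4 oracles, architecture contracts on
one full-width 256×256 forward pass, and learning behaviour by
overfitting the lightweight configuration (widths `[8,16,32,64,128]`)
on eight synthetic 64×64 images — reaching train Dice ≥ 0.95 within
200 full-batch epochs at `lr0 = 1e-3` (cosine to 1e-5) in at least two
of three fixed seeds. These sizes were chosen as the smallest
configurations that still exercise every code path end to end; the
acceptance script trains the same lightweight variant on a 40-image
synthetic dataset with a 70/15/15 split and reports held-out metrics.

## Known limitations

* CPU-scale only; no GPU, no mixed precision, no distributed training.
* Binary segmentation only (single-channel sigmoid head); no deep
  supervision; no 3-D variant.
* The synthetic generator is a stand-in for real dermoscopy data, as
  discussed above.
* Printed efficiency figures of the original architecture family
  (parameter totals, FLOPs) are not reproduction targets; the package
  reports its own exact counts instead.
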