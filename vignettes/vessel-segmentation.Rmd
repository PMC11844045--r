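---
title: "Retinal vessel segmentation with double-attention residual U-blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal vessel segmentation with double-attention residual U-blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darsunet)
```

## The problem and the model

Retinal vessel morphology (calibre, tortuosity, branching) carries
diagnostic signal for ophthalmic and cardiovascular disease, and
segmenting the vasculature from fundus photographs is the step that makes
it measurable. Vessels are thin, densely branched, low-contrast
curvilinear structures on a textured background, which is why generic
encoder–decoder segmenters lose the finest branches.

`darsunet` implements a two-level nested U-architecture for this task.
The outer U has six encoder stages and five decoder stages; every stage
is itself a small residual U-block (RSU), so the network extracts
multi-scale features at every resolution level. The stage plan is fixed:
stages 1–4 use U-blocks of depth 7, 6, 5, and 4; the two deepest encoder
stages and the deepest decoder stage use a dilated depth-4 variant (the
"4F" bottleneck) in which 2×2 max pooling is replaced by dilated
convolutions with rates 2, 4, and 8, because at 1/16–1/32 resolution
further resampling destroys what little spatial detail remains. Along one
axis the dilated encoder chain of 3×3 kernels (dilations 1, 2, 4, 8) sees
`1 + 2*(1+2+4+8) = 31` pixels, which `dilatedReceptiveField()` verifies
by gradient support.

Each block is made *double-attentive* by two mechanisms:

* **Attention gates on every skip connection.** The skip feature `x` and
  the deeper gating feature `g` are projected by 1×1 convolutions to an
  intermediate width, summed (after bilinear upsampling of the gating
  projection when `g` is at half resolution), passed through ReLU, a 1×1
  convolution to one channel, and a sigmoid. The resulting coefficient
  map multiplies `x` before concatenation, so uninformative background
  regions of the skip are suppressed. A depth-`L` block carries `L - 2`
  gates, one per skip.
* **CBAM on the block output.** High-resolution blocks (depths 4–7) end
  with spatial attention (SAM: per-pixel mean/max over channels, a 7×7
  convolution, sigmoid); the dilated bottleneck blocks end with channel
  attention (CAM: global mean/max pooling through a shared two-layer
  bottleneck transform, summed, sigmoid), since at very low resolution
  spatial attention has little left to attend to.

The block output is added to a 3×3 projection of the block input (the
residual connection), and every decoder stage plus the deepest encoder
emits a single-channel side output that is upsampled to input size. The
six side logits are fused by a 1×1 convolution into the final map; all
seven maps receive the loss (deep supervision), which keeps gradients
strong in the deepest stages.

## Loss and metrics

Training minimizes, for each of the seven maps, the sum of the soft Dice
loss

$$\mathcal{L}_{Dice} = 1 - \frac{2\sum_i y_i \hat y_i + \varepsilon}
{\sum_i y_i + \sum_i \hat y_i + \varepsilon}$$

and the full binary cross-entropy
$-\tfrac1N \sum_i [y_i \log \hat y_i + (1-y_i)\log(1-\hat y_i)]$.
Dice drives overlap of the (minority) vessel class but saturates on fine
detail; cross-entropy scores every pixel equally and complements it. We
deliberately use the two-class cross-entropy rather than a
positives-only sum: a positives-only form ignores background pixels
entirely, which contradicts the purpose of adding the term. The Dice
smoothing constant is `1e-6` (guards 0/0 on empty masks) and
probabilities are clipped to `[1e-7, 1 - 1e-7]` inside the log.

Evaluation pools pixel confusion counts over the test set (per-image
values are also reported) and derives accuracy, sensitivity,
specificity, F1, and mean IoU (averaged over the vessel and background
classes). FOV restriction of the counts is available but off by default.

## The compute engine

No deep-learning framework is used: the package ships a small
reverse-mode autodiff engine over `[H, W, C, N]` arrays with C++ kernels
(im2col + GEMM convolutions with dilation, 2×2 max pooling, bilinear
resizing) and R-level batch normalization, attention, and loss nodes.
Numerical conventions worth knowing:

* Batch normalization uses biased batch variance with `eps = 1e-5` and
  running-moment momentum 0.1; evaluation mode uses the stored moments,
  which makes evaluation forwards bitwise repeatable.
* Bilinear resizing uses the half-pixel (`align_corners = FALSE`)
  convention; its backward pass is the exact transpose.
* Max-pooling routes the gradient to the first maximum; the channel/global
  max-pooling nodes inside the attention modules split the gradient
  equally among ties (a valid subgradient; ties only occur on degenerate
  constant inputs).
* Weights are initialized with a truncated-normal He scheme (draws
  clamped at ±2 sd), reproducible from the build seed.
* The optimizer is Adam (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`)
  with L2 weight decay coupled into the gradient.

Training defaults follow the reference recipe: batch size 2, initial
learning rate 0.001, weight decay 1e-4, 100 epochs, no learning-rate
schedule (a constant rate; the config exposes the epochs/iteration cap
instead). Whole images are trained on directly — no patch extraction —
after zero-padding to multiples of 32.

## Design choices where the architecture was open

* **Gate combination.** The gate's coefficient map *multiplies* the skip
  feature (standard attention-gate semantics). The single-channel
  coefficient is broadcast across channels.
* **Gate width.** The intermediate width `F_int` defaults to half the
  skip's channels (at least 1).
* **Block internals.** A depth-`L` block is: input projection `f0` (to
  the block's output width), `L-1` encoder conv units (each
  Conv3×3 + BN + ReLU) with `L-2` poolings between them, and `L-2` gated
  decoder levels; the top decoder maps back to the output width. SAM/CAM
  are applied to the decoder output *before* the residual addition.
* **4F skips.** In the dilated variant all features share one
  resolution, so gating happens at equal size and concatenation uses the
  deeper feature directly (no upsampling term).
* **Channel plan.** Encoder output widths are
  `baseWidth * (1, 2, 4, 8, 8, 8)` with mirrored decoders and block-mid
  widths of half the output width — the usual nested-U convention, scaled
  down by `baseWidth` for desk-scale work.
* **Side outputs.** The deepest encoder contributes a side output and
  participates in fusion and the loss, together with the five decoders.
* **Downsampling between stages** is 2×2 max pooling (matching the
  blocks' internal vocabulary), upsampling is parameter-free bilinear
  interpolation.

## Preprocessing and augmentation

Color fundus images are reduced to the green channel (highest
vessel/background contrast), normalized to `[0, 1]`, contrast-enhanced
with CLAHE (clip limit 2.0, 8×8 tiles; inputs are mirror-padded to tile
multiples and cropped back), and gamma-transformed (`gamma = 1.2` by
default; the exponent is exposed since reasonable fundus pipelines use
values near 1). The composition order is fixed: green → normalize →
CLAHE → gamma.

Augmentation is exact bookkeeping rather than random sampling: flips
multiply a dataset by 4 (original, horizontal, vertical, both) and
translations by 5 (original plus one 50-pixel shift in each cardinal
direction, zero-filled), which takes 40 sources to 160 and 800, and 28
sources to 112 and 560. The translation magnitude is interpreted as a
50-pixel shift; zero fill plus FOV masking is the least surprising
treatment of the vacated band. The 4:1 train/test split is grouped by
source image so no augmented variant of a test image can leak into
training — a control the bookkeeping makes essentially free.

## The phantom generator

`generatePhantom()` emulates the *structure* of a fundus photograph: a
circular field of view (radius 0.48 of the image side), a smooth radial
background (brighter at the centre), Gaussian sensor noise
(sd 0.03), and darker curvilinear vessel trees (intensity drop 0.35)
grown as seeded random walks from roots on the FOV rim. Each unit step
jitters the heading (sd 0.15 rad), stamps a disk of the current width
(roots 3 px), and may branch (probability 0.05/step) into a child at 0.7×
width; children below 1 px are pruned, and every branch carries a step
budget (roots about two FOV radii, children a fraction of the parent's
remainder) so trees taper and terminate like real vasculature instead of
filling the disk. At the 128-px default these settings yield vessel
densities of roughly 13–21% of the FOV across seeds, in the range of real
fundus benchmarks. Images are quantized to 8 bits in memory so the
on-disk PNG representation is exact, and the whole phantom is a pure
function of its seed.

What the phantoms deliberately do **not** model: optic disc and macula,
pathology (exudates, hemorrhages), vessel central reflex, chromatic
information, and inter-image illumination variation. Passing the
desk-scale tests therefore demonstrates that the architecture, gradients,
and pipeline work end-to-end and that the network can learn curvilinear
structure from realistic contrast — it says nothing about clinical-grade
accuracy on real fundus datasets, which requires full-width training on
the public benchmarks.

## Problem sizes used by the tests

The shipped checks run at desk scale by choice: `baseWidth = 4`
(≈ 2 × 10^5 parameters), eight 64-px phantoms, batch 2, at most 200
gradient steps for the learning check, and `baseWidth = 2` for the pure
shape/contract tests. Full-scale work would use `baseWidth` 32–64 and the
public datasets; nothing in the code changes except the configuration.

## A worked desk-scale example

```{r example, eval = FALSE}
train <- lapply(generateDataset(8, baseSeed = 101, size = 64),
                preprocessSample)
fit <- trainNetwork(train,
                    trainConfig(maxIterations = 200, epochs = 100,
                                valFraction = 0, seed = 7),
                    networkConfig(baseWidth = 4))
held <- lapply(generateDataset(4, baseSeed = 1001, size = 64),
               preprocessSample)
pred <- predictNetwork(fit$net, held)
evaluateSegmentation(lapply(pred, `[[`, "mask"),
                     setNames(lapply(held, sampleMask), names(pred)),
                     setNames(lapply(held, sampleFOV), names(pred)))$metrics
```

## Known limitations

* Single CPU, double precision, no SIMD/GPU path: full-width training on
  real datasets is out of reach of the shipped engine and out of scope.
* Binary segmentation only; no multi-class or 3-D support.
* The batch-norm statistics are per-process state; training the same
  network object twice without rebuilding continues from the updated
  moments (rebuild from the seed for a fresh start).
* Metrics are pixel-based; connectivity/centerline metrics are not
  implemented.
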