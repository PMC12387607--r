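---
title: "Methods: dual-path nuclei segmentation with test-time augmentation"
author: "nucseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-path nuclei segmentation with test-time augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucseg)
```

## The problem

Hematoxylin–eosin (H&E) stained skin histopathology shows cell nuclei in
blue–purple and cytoplasm/connective tissue in pink.  Diagnosis of
cutaneous melanoma rests on finding malignant melanocyte nuclei — larger,
more irregular and more clustered than benign nuclei — inside gigapixel
slides.  `nucseg` segments RGB tiles pixelwise into three classes
(1 = melanoma nuclei, 2 = non-melanoma nuclei, 3 = background) and then
extracts coherent melanoma regions from the class map.

The pipeline has five stages:

1. **Colour normalization.** Every channel is z-scored by *global*
   statistics of the training split,
   $x_{\mathrm{norm}}(m,n,c) = (x(m,n,c) - \mu_c)/\delta_c$, with
   $\mu_c, \delta_c$ the pooled mean and population standard deviation of
   channel $c$ over all training pixels.  Using dataset-global rather than
   per-image statistics keeps training and test tiles on a common scale; an
   $\varepsilon$-floor of $10^{-8}$ on $\delta_c$ keeps degenerate constant
   channels finite.
2. **Test-time augmentation.** Each test tile spawns five views: the
   original, its clockwise rotations by 90°, 180° and 270°, and an
   edge-enhanced image $x_{\mathrm{enh}} = \mathrm{clip}(x * h + \alpha\,
   x_{\mathrm{edge}},\, 0, 255)$ where $h$ is a $3\times3$ Gaussian
   low-pass kernel applied per channel, $x_{\mathrm{edge}}$ a binary Canny
   edge mask of the luminance, and $\alpha = 20$ intensity units.
3. **Dual-path CNN.** A fully convolutional classifier maps each
   normalized view to per-pixel class probabilities via softmax.
4. **Ensembling.** The five per-view probability maps are mapped back to
   the original pixel grid (counter-rotations; the enhanced view is
   geometrically the identity) and combined by probability averaging or
   majority voting.
5. **Melanoma region detection.** The melanoma class mask is cleaned by
   dilation, hole filling, erosion and a minimum-area threshold.

## The network

The classifier has two feature-extraction paths fused before softmax:

* the **detailed path (DFE)** keeps full resolution throughout: nine
  conv+batch-norm+ReLU layers with kernels between 1×1 and 5×5 and a
  concatenation of the two preceding layer outputs after every pair of
  layers (no pooling anywhere);
* the **coarse path (CFE)** is a U-shaped encoder–decoder with kernels
  between 5×5 and 23×23: four conv+BN+ReLU+2×2-max-pool levels down, two
  bottleneck convolutions at 1/16 resolution, and four levels of
  2×2-nearest-neighbour upsampling + skip concatenation + convolution back
  up.  The large kernels live at the coarse levels, where they are cheap;
* the **fusion block** concatenates the raw input (a skip connection), the
  DFE output and the CFE output, and applies a 3×3 convolution (13
  filters, ReLU) followed by a 1×1 convolution to the 3 class logits.

Kernel sizes and filter counts per layer are not free: they were fixed
once by constraint-solving inside the ranges above (at most 64 filters per
layer) so that the trainable-parameter total is exactly **152,401**,
splitting into 41,133 (DFE) + 101,268 (CFE) + 10,000 (fusion) under the
counting convention *convolution weights + convolution biases + one
batch-norm scale and shift per channel* (running statistics are not
trainable and not counted).  The solved table ships as the default
`dpnet_config()` and is printed by `network_layer_table()`.

Two structural choices deserve a note.  First, the coarse path's ten
convolutions are arranged 4 down + 2 bottleneck + 4 up; the bottleneck
placement is the standard U-Net shape and matches the path's four skip
connections.  Second, the two fusion convolutions carry **no batch norm**:
under the counting convention any fusion block of the form
$h(k_1^2 c_{\mathrm{in}} + 3 + 3k_2^2) + 3$ forces $h = 13$ (because
$9997 = 13 \times 769$), and no odd kernel pair admits an exact 10,000
with the extra $3h$ batch-norm term.  Dropping normalization on the two
layers directly in front of softmax is harmless and admits the exact
solution $9\cdot85\cdot13 + 13 + 3\cdot13 + 3 = 10{,}000$.

Inputs must have spatial dims divisible by 16 (four halvings); arbitrary
images are mirror-padded and cut into non-overlapping 64×64 blocks, and
the stitched output is cropped back.  A 960×960 tile becomes 225 blocks.

## Training

`fit_dpnet()` minimizes class-frequency-weighted categorical cross-entropy
(weights $n_{\mathrm{total}}/(3 n_c)$, so rare melanoma pixels are not
drowned out) with Adam, defaults: learning rate $10^{-3}$, batch 32, 50
epochs.  Weight init is He-normal.  All randomness — initialization and
epoch shuffling — derives from one integer seed, so a run is bit
reproducible on one machine.  Batch-norm uses per-batch statistics with
momentum 0.1 for the running estimates used at inference.

The engine is written in C++ (im2col + GEMM convolutions, single
precision).  It exists because no deep-learning framework is available to
this package's dependency set, and because the network itself — not a
wrapper around one — is the artifact the package implements.

## Ensembling rules

*Averaging*: $P_{\mathrm{av}} = \tfrac1N \sum_i P_i$, class =
$\arg\max_c P_{\mathrm{av}}$; argmax ties break to the lowest class index,
deterministically.  *Voting*: each view votes with its argmax class; the
modal class wins; pixels with tied vote counts fall back to the averaging
rule at that pixel.  With $N = 3$ the views are the original and the
90°/270° rotations; $N = 5$ uses all views.

The correctness of the coordinate bookkeeping is tested with an exactly
rotation-equivariant stand-in predictor (`color_rule_classifier()`, a
per-pixel nearest-colour rule emitting one-hot probabilities): for such a
predictor both ensemble modes must return the single-pass segmentation
bit-for-bit, for both $N = 3$ and $N = 5$.

## Morphology

`apply_morphology()` applies, in order: binary dilation (disk structuring
element, default radius 2), hole filling, binary erosion (disk, radius 2),
and removal of connected components below 100 px.  Connectivity is
8-connected throughout, including the background flood fill that defines
holes; pixels outside the image are background, so erosion shrinks regions
touching the border.  The radii and area threshold are package defaults —
the source method names the chain but no sizes — and all are exposed in
`morphology_params()`.  "Threshold" is read as minimum-area filtering
since the input mask is already binary.  The test suite checks every
operation against brute-force set-definition oracles on random masks.

## Edge detection choices

The Canny stage is pinned for bit-stability: luminance
$0.299R + 0.587G + 0.114B$; Gaussian smoothing $\sigma = 1$ (radius
$\lceil 3\sigma \rceil$, mirror boundary); Sobel gradients; non-maximum
suppression with the gradient direction quantized to four bins (ties
kept); hysteresis thresholds at 0.10/0.20 of the maximum gradient
magnitude with 8-connected linking.  Gradient maxima below $10^{-6}$
intensity units are treated as numerically flat, so constant images
produce empty masks.  The enhancement kernel is the binomial
$(1,2,1)\otimes(1,2,1)/16$; the edge term is added *after* low-pass
filtering (reading the defining expression left to right), and the result
is clipped to $[0,255]$.

## The synthetic data generator

Real melanoma slides of the kind this pipeline targets are not publicly
deposited, so the package ships a generator whose output exercises every
stage with exact ground truth: a pink background (mean RGB 230/185/205),
Poisson(6) near-circular blue-purple non-melanoma nuclei (mean RGB
95/70/150, radius U(3,6) px, axis ratio U(0.85,1), minimum-separation
placement with a retry bound), and three larger, darker, more elongated
melanoma nuclei (mean RGB 70/50/120, radius U(5,9), axis ratio U(0.5,0.9))
scattered around a single Gaussian cluster centre (sd 14 px) — melanoma
regions are spatially coherent, which is what the morphology stage
presumes.  Per-nucleus colour jitter is ±15; pixel noise is Gaussian with
sd 8; melanoma is painted last so it wins overlaps deterministically.

Ellipses are parameterized so the area is $\pi r^2$ independent of the
axis ratio, which makes the expected melanoma area fraction analytic
($n_{\mathrm{mel}}\,\pi\,\mathbb{E}[r^2]/S^2$, about 11.6% for the 64×64
defaults) and testable.  What the generator does **not** emulate: stain
variability between labs, chromatin texture inside nuclei, cytoplasm
structure, touching-nuclei boundaries, or slide-level artefacts.  Passing
tests on synthetic tiles therefore demonstrates that the machinery —
normalization, augmentation geometry, network capacity, ensembling,
morphology, metrics — is correct, not that the trained weights transfer
to real tissue.

## Desk-scale study sizes

The test suite trains the full 152,401-parameter network on 200 synthetic
64×64 patches (batch 16, 6 epochs, Adam $10^{-3}$) and evaluates on 50
held-out patches; with these sizes the held-out nuclei-vs-background Dice
reaches ≈0.95 by epoch 4–6, comfortably above the 0.80 bar the suite
asserts, and the run is reproducible from its seed.  Five training seeds
are used to check the directional claim that 5-view probability-averaging
TTA does not degrade the Dice (allowing 0.01 slack, at least 4 of 5
seeds).  These sizes are the package's choice of a small but
representative study; `fit_dpnet()` defaults remain 50 epochs/batch 32
for real use.

## Evaluation conventions

Metrics come from per-pixel confusion counts: accuracy, precision,
recall, Dice $= 2PR/(P+R) = 2\,TP/(2\,TP+FP+FN)$ and Jaccard
$= TP/(TP+FP+FN) = D/(2-D)$.  Two binarizations are supported and always
named in the report: *nuclei* (classes 1+2 vs 3, the nuclei-segmentation
view) and *melanoma* (class 1 vs rest, the region-detection view).
Percentages print at two decimals with half-up rounding.  A metric with a
zero denominator is reported as `NaN` with a warning — never silently 0,
which would inflate averages.

## Known limitations

* Training is CPU-bound and single-threaded by design of the environment;
  wall-clock scales linearly in epochs × patches.
* Batch-norm inference uses running statistics, so predictions depend
  (deterministically) on the training batch ordering.
* The voting rule's tie-break uses the averaging rule at the tied pixel;
  an alternative reading (averaging over spatial neighbours) exists in
  the literature this follows, but is ambiguous and not implemented.
* Quarter-turn rotations and one enhancement are the only augmentations;
  flips, crops and scalings are out of scope.
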