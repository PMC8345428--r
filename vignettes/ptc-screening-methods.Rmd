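---
title: "Whole-slide PTC screening: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-slide PTC screening: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Papillary thyroid carcinoma (PTC) is the most common thyroid malignancy, and
its primary diagnostic route — visual inspection of papanicolaou-stained
cytology slides (fine-needle-aspiration smears and ThinPrep preparations) —
is slow and subject to inter-observer variability. Digitized at 20x, a
cytological whole-slide image (WSI) runs to billions of pixels, so any
practical automated screen must avoid touching most of them. `ptcscreen`
implements a fast screening pipeline with three ideas:

1. **Hierarchical tiling.** The slide is partitioned into non-overlapping
   512-px square tiles at scan magnification (level 0). Tiling is pure
   bookkeeping: `ceil(width / 512) x ceil(height / 512)` tiles, edge tiles
   smaller, every pixel in exactly one tile.
2. **Fast background filtering.** Most of a cytology slide is bare glass.
   A thumbnail at 1/32 scale is thresholded in HSV saturation; tiles whose
   footprint holds less than 5% tissue are discarded *before* inference and
   contribute background to the output mask at zero cost.
3. **A fully convolutional segmenter.** Kept tiles pass through a
   padded-VGG16 FCN-32s network that scores every pixel for three classes
   (background / non-PTC material / PTC); per-tile argmax class maps are
   stitched back into a whole-slide PTC mask.

## The network

The segmenter is VGG16 recast as a fully convolutional network:

| stage | operation | size rule |
|---|---|---|
| padding | zero-pad 100 px per side | 512 → 712 |
| conv1_1 | 3x3, **valid** | 712 → 710 |
| conv1_2 … conv5_3 | 3x3, pad 1 | size preserved |
| pool1 … pool5 | 2x2 stride 2, **ceil mode** | 710 → 355 → 178 → 89 → 45 → 23 |
| conv6 | 7x7, valid (fc-converted), dropout | 23 → 17 |
| conv7, conv8 | 1x1, dropout after conv7 | 17 |
| deconv9 | 64x64 transposed conv, stride 32 | 17 → 576 |
| crop | centered, offset 32 | 576 → 512 |

Three structural choices are forced by the printed size chain: the 100-px
pad (512 → 712), the valid first convolution (712 → 710), and ceil-mode
pooling (355 → 178, 89 → 45, 45 → 23). Two are not, and were decided here:

* **Crop alignment.** The upsampled score map is 576 px for a 512-px input
  and only a 512-px crop is specified. We crop symmetrically (offset 32 per
  side), which matches the symmetric 100-px pad; the classical FCN offset of
  19 is available via `fcn_config(crop_offset = "fcn")`.
* **Class semantics.** The scoring convolution has three channels but the
  class meanings are conventions of this package: 0 = background,
  1 = non-PTC cellular material, 2 = PTC. Evaluation treats label 2 as the
  positive class. Argmax ties break toward the lowest index, i.e. toward
  background — deterministic and conservative.

`shape_trace()` propagates these rules analytically for any input size and
is checked against the instantiated network's empirical tensor shapes.

Because no deep-learning framework is available to R in this stack, the
network — im2col convolutions backed by BLAS, ceil-mode pooling, the
transposed convolution, and the full backward pass — is implemented in
compiled code inside the package (`src/convnet.cpp`). Gradients of every
primitive are verified against central differences in the test suite.

A `width_multiplier` scales all channel widths (rounded up, minimum 1)
without touching spatial geometry. At `1/64` the network keeps the exact
layer structure at ~70k parameters and runs a 512-px tile in about a quarter
second on one CPU core, which is what the test suite uses; spatial shapes
are provably identical to the full-width network.

## Training

`training_config()` defaults encode the screening recipe: SGD with learning
rate `1e-10`, dropout `0.5`, weight decay `5e-4`. Choices the recipe leaves
open, fixed here:

* **Loss reduction.** Default `"sum"` per image: a learning rate of 1e-10
  is only sensible against a per-image *summed* cross-entropy (the original
  FCN convention, where per-image loss magnitudes are ~1e5). `"mean"` with
  a correspondingly larger rate is provided for desk-scale experiments.
* **Momentum 0.99** (the heavy-momentum convention paired with tiny rates),
  batch size 1 (full-image batches), coupled L2 decay inside the update —
  so one step with zero data gradient shrinks every weight by exactly
  `1 - lr * decay`, which the tests assert.
* **Initialization.** `pretrained_backbone` copies published VGG16 weights
  where shapes permit, zeroes the scoring convolution, and sets the
  transposed convolution to the closed-form separable bilinear kernel
  (`bilinear_kernel(64)`); when no weight file is supplied it falls back to
  He-normal random initialization with a warning rather than failing,
  keeping the package fully usable offline.
* Epoch count, train/validation split and augmentation are deliberately
  plain configuration with no claimed defaults: the original recipe does
  not state them.

Dropout masks draw from R's RNG under the training seed, so two runs with
the same seed, model and samples produce bitwise-identical loss traces.

## Background filter

The filter's original specification is not public; this package implements
the standard digital-pathology tissue detector and claims only the
*contract* — background tiles are skipped, tissue tiles are kept:

* thumbnail at downsample 32 (read from the coarsest usable pyramid level,
  never from level-0 tiles);
* tissue = HSV saturation above a threshold **and** brightness below
  250/255 (the glass/air guard). The threshold comes from Otsu's method on
  the saturation histogram, falling back to a fixed floor (~0.098) with a
  warning when the thumbnail is degenerate (e.g. an empty slide);
* a tile is kept when ≥ 5% of its thumbnail footprint is tissue.

All three constants live in `filter_config()`. Keeping the threshold list
small and the computation thumbnail-only is what makes filtering effectively
free: its cost is `(W/32) x (H/32)` pixels per slide. Raising
`tissue_fraction_min` can only shrink the kept set (a monotonicity the tests
check), and `tissue_fraction_min = 0` keeps every tile, which is how the
filter-off equivalence test demonstrates that filtering suppresses
predictions but never alters them.

## Synthetic slides

Clinical slides are not distributable, so the package generates
papanicolaou-like fixtures: a bright gray background (245 ± 5, jittered
*equally* across channels so its saturation is exactly zero) with
non-overlapping ellipsoidal cell clusters of two classes — PTC dark violet
(110, 50, 140) and benign pale blue (165, 200, 235) — with Gaussian interior
texture (sd 8) and exact per-pixel truth recorded at paint time. Default
cluster semi-axes are 60–180 px, a plausible range for cell groups at 20x.
The colors are chosen so saturation separates tissue from background by
construction (the benign blue still sits above any sensible threshold), and
slides are written as multi-page pyramidal TIFFs so the gigapixel code path
is the one exercised.

What the fixtures do **not** emulate: nuclear morphology (grooves,
pseudoinclusions), stain variability, smear artifacts, pen marks, or
out-of-focus regions. Passing tests therefore demonstrate the pipeline's
mechanics — tiling, filtering, inference plumbing, stitching, metrics — and
the network's ability to learn color/texture-separable classes; they say
nothing about clinical discrimination on real cytology, whose headline
accuracy is explicitly not reproduced here.

### Resolution limits of the learning smoke test

The training smoke test asks a 1/64-width network to reach foreground IoU
≥ 0.7 on held blob tiles within a few CPU-minutes. FCN-32s recovers spatial
detail through a single stride-32 upsampling, so boundary localization error
is on the order of half the stride (~16 px). For a disc of radius r the
achievable IoU is roughly `((r-16)/(r+16))^2` — about 0.5 at r = 60 but
0.85 at r = 180. The smoke test therefore uses *two-color* blob tiles — stained clusters of
one color on the bright background — with 180–260 px semi-axes, comfortably
above the network's resolution floor; both choices reflect what the
architecture can resolve in minutes of CPU training, not a tuning of the
acceptance threshold. The smoke recipe is `loss_reduction = "mean"`,
learning rate 0.01, momentum 0.9, dropout 0.5, 90 epochs over 8 tiles
(~4.5 CPU-minutes). The three-class task (adding the paler benign color)
trains the same way but converges more slowly than a CPU-minutes budget
allows at 1/64 width; the screening examples in the test suite exercise the
three-class head through forced logits instead.

One caveat is stated plainly: at 1/64 width the time to escape the initial
"predict everything background" plateau varies severalfold across random
initializations. The pinned test configuration converges well within the
budget; some other draws need more epochs than a CPU-minutes budget allows.
This is a property of very narrow deep networks, and the stain-positive
first-layer initialization below shortens — but does not equalize — the
plateau.

### Input representation and bias initialization

Tiles enter the network as *stain darkness*, `1 - x/255`: bare glass maps
to ~0 and absorbing (stained) material is positive, the usual bright-field
optical-density convention. This matters most at tiny widths: the first
convolution of a 1/64-width network has a single ReLU channel, and with a
representation in which the bright background dominates the pre-activation,
that unit can clamp both background and weakly stained material to zero at
initialization — their gradients then stay frozen and pale classes are
never learned. With darkness-positive input and a small positive bias
(+0.1, applied to every ReLU-bearing convolution under random
initialization), every unit starts active and faint stain contrast survives
the first layer. The linear scoring convolution keeps a zero bias.

The first convolution additionally draws its weights *half*-normal
(`|N(0, 2/fan_in)|`): on an absorbance input the first layer acts as a
stain-unmixing filter, and Beer–Lambert additivity makes physical stain
combinations non-negative. A non-negative first layer guarantees that
stained material produces a monotone response whatever the draw, which
matters when the layer has only one or two channels.

## Evaluation machinery

Per-slide confusion counts stream over tile-sized blocks (exact, never
holding two full slides of intermediate logicals), with PTC (label 2) as the
positive class and labels 0/1 merged as negative. Metrics follow the usual
formulas with two conventions for degenerate slides: a perfectly predicted
all-background slide scores 1 on precision/recall/F1/Jaccard (so empty
synthetic slides are scoreable), and any other empty denominator scores 0.
The identity `F1 = 2J/(1+J)` is asserted on every record.

Cohort summaries are **macro averages** (per-slide metrics averaged across
slides), the reading most consistent with reporting per-slide distributions;
pooled-pixel micro averaging is available behind `micro = TRUE`.

Method comparison uses Fisher's LSD: one-way ANOVA pooled MSE with `N - k`
degrees of freedom, unadjusted pairwise t tests
`t = (m_I - m_J) / sqrt(MSE (1/n_I + 1/n_J))`, and 95% CIs
`diff ± t_{0.975,df} SE`. The pooled MSE comes from `stats::aov`; the test
suite checks every pairwise row against an explicit sums-of-squares oracle
to 1e-10. Zero within-group variance is flagged degenerate rather than
silently producing p = 0.

## Numerical and I/O choices

* Slides and masks are 8-bit; masks round-trip losslessly through
  single-channel LZW TIFF. Multi-channel TIFF pages decode to normalized
  doubles and are rescaled by 255 with exact rounding.
* Edge tiles are reflect-padded (periodic symmetric extension) to the
  network input only at inference; predictions are cropped back to the true
  extent before stitching. Stitching is non-overlapping by construction and
  errors on overlapping input rather than blending.
* Inputs use the stain-darkness scale `1 - x/255` (see above); with random
  initialization no channel-mean subtraction is warranted.
* Problem sizes in the test suite — ≤ 2048² fixtures, 1/64-width models,
  ≤ 25-epoch smoke training — were chosen so the whole suite exercises every
  code path, including one full-width forward pass, in well under half an
  hour on a single core.

## Known limitations

* Only TIFF-cored slide formats are read; vendor containers (SVS beyond its
  TIFF core, MRXS) are out of scope, as are stain normalization and
  multi-level inference.
* The BigTIFF write path for masks beyond 2^31 pixels is not provided by
  the available TIFF writer; masks at desk scale are ordinary TIFFs.
* The background filter claims behavioral equivalence with its contract
  (background tiles skipped), not with the unpublished original filter.
* Training at full width on CPU is possible but slow; the package is
  faithful to the architecture, not to GPU wall-clock figures.
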