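---
title: "Segmenting and counting mixed cell images with auto-generated labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and counting mixed cell images with auto-generated labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellseg)
```

## The problem

Counting red blood cells (RBCs) and macrophages in bright-field
microscopy images is a semantic-segmentation problem: label every pixel
background (0), RBC (1) or macrophage (2), then count connected
regions per class.  Convolutional segmenters do this well but need many
pixel-wise annotations, which are expensive to produce.  `cellseg`
implements a label-economical training strategy:

1. **Auto-labeling.**  Images that contain only one kind of cell can be
   labelled by classical image processing: Gaussian smoothing, adaptive
   thresholding, border-following contour extraction with small-area
   removal, and (for adhesive cells) morphological opening.  The result
   is a training mask obtained without any human annotation.
2. **Pretraining (U-Single).**  A U-Net is trained on the auto-labelled
   single-kind images with the combined loss `L = H − log J` (pixel
   cross-entropy plus a soft-Jaccard term).
3. **Fine-tuning (U-Transfer).**  The pretrained network is fine-tuned
   on a small manually labelled mixed-cell set at half the learning
   rate, all layers trainable.
4. **Counting.**  Predicted masks are cleaned by a per-class minimum
   area filter and cells are counted as 8-connected components.

A fully supervised baseline trained on many labelled mixed images
(U-Base) bounds what the shortcut can hope to achieve.

## The synthetic scene generator

The real data behind this procedure is not redistributable, so the
package ships a seeded generator (`synth_config()`, `generate_scene()`)
that emulates its statistical structure and provides exact ground
truth.  Scenes are square 8-bit images containing:

* **RBC-like cells** — small, near-circular ellipses (default radius
  4–6 px at 256×256), mean intensity 100;
* **macrophage-like cells** — larger ellipses (radius 10–16 px,
  preserving the ≈2.5× physical size ratio of 13–20 µm vs 5–7 µm cells;
  the px/µm scale is a free parameter), mean intensity 70;
* a background plane at 180 with a random **linear illumination
  gradient** (default amplitude 20 across the frame) and additive
  Gaussian **sensor noise** (default sd 10);
* per-cell uniform intensity jitter (±10), eccentricity jitter and
  random orientation.

Placement is rejection-sampled so that every cell mask is 8-disconnected
from every other (components of the truth mask equal the true counts).
**Adhesive macrophages** are placed rim-to-rim with a previous
macrophage, separated by a ~2 px gap; the *image* additionally renders a
darkened optical contact zone (`adhesion_bridge`, default half-width
2 px) between the pair, while the *mask* keeps the two instances apart,
as an annotator would draw them.  Thresholding therefore sees one merged
blob with a thin neck — the artifact that morphological opening is meant
to repair — while the ground truth remains countable.  Chains of
adhesive cells can enclose interstitial background, which hole-closing
contour filling would wrongly fill without the opening step.

Two contracts make the generator testable: determinism (same seed, bit
identical scenes) and separability (with zero noise and zero gradient, a
global threshold at the midpoint between cell and background means,
`separation_threshold()`, recovers the foreground exactly).

What the generator does **not** emulate: point-spread-function optics,
out-of-focus blur, debris and staining variability, partial cells at the
frame border (cells are placed fully inside), or overlapping cells.
Passing tests on synthetic scenes therefore demonstrate the internal
consistency of the pipeline under controlled conditions, not performance
on real microscopy data.

## Auto-labeling: parameters and numerical choices

`autolabel_image()` runs the five-stage pipeline.  The tunable
parameters, their defaults and rationale:

| parameter | default | role |
|---|---|---|
| `gauss_size`, `gauss_sigma` | 3×3, σ = 0.8 per axis | denoising before thresholding |
| `window` | 3 (preset: `2·max_radius + 1`) | adaptive-threshold window |
| `offset` (C) | 2 (preset: contrast/8) | subtracted from the local weighted mean |
| `window_sigma` | OpenCV convention (preset: `window/2`) | Gaussian weighting of the window |
| `min_area` | 25 px (preset: half the minimum true cell area) | debris removal |
| `morphology` | off (preset: on for macrophages) | opening to split adhesive cells |
| `morph_size`, `morph_shape` | 3×3 square (preset: disk of radius `min_radius/2`) | structuring element |

Numerical conventions are fixed and tested: convolution and adaptive
thresholding use symmetric (half-sample) border reflection; erosion and
dilation use replicate padding with the anchor at the kernel centre; a
pixel is foreground only if strictly below (darker polarity) the local
threshold — ties go to background; intensities are rounded half away
from zero and clamped to [0, 255]; contours are the outermost borders of
8-connected components, traced clockwise from the top-left-most pixel,
and contour filling closes holes.  Cell polarity (darker or lighter than
background) is a configuration switch throughout.

Design choices where the procedure was genuinely open:

* **Window weighting.**  A 3×3 Gaussian-weighted window is extremely
  local; for cells of known size the matched preset uses
  `window = 2·max_radius + 1` with near-uniform weights
  (`window_sigma = window/2`), so the windowed mean estimates the local
  *background* level rather than the cell interior.  With the narrow
  default weighting, the threshold tracks the cell's own intensity and
  systematically erodes cell boundaries.
* **Offset.**  The preset uses an eighth of the cell–background
  contrast: about 2 standard deviations of the smoothed default noise,
  yet small enough that the detected boundary stays near the
  half-contrast level set.  Residual background speckle is removed by
  the minimum-area filter, so the offset does not need to suppress noise
  on its own.
* **Morphology on the binary mask.**  Erosion and dilation are defined
  for grayscale images in general, but "opening a set of contours" is
  not; opening is applied to the filled binary mask of the detected
  contours, after which contours are re-extracted and re-filtered.
* **Structuring element.**  The classical 3×3 square is the default.
  The preset uses a digital disk of radius half the *minimum* cell
  radius: the largest disk guaranteed to fit inside every cell (the
  boundary curvature radius of the generated ellipses exceeds it), so
  opening cuts adhesion necks without eroding cell bodies.  A square of
  that size would shave diagonal boundary steps.
* **Area filter.**  Filled area (holes closed) is used, not boundary
  length.

## The network

`unet_config()` describes an encoder–decoder with skip connections:
per encoder stage two 3×3 same-padding convolutions (ReLU after each)
followed by 2×2 stride-2 max pooling; a two-convolution bottleneck; per
decoder stage nearest-neighbour 2× upsampling, a channel-halving
convolution, concatenation with the same-level encoder output, and two
further convolutions; a final 1×1 convolution to the class scores.  No
batch normalisation.  The default widths 32→512 make the final decoder
width 32.  An `encoder = "vgg16"` preset substitutes the standard
13-convolution VGG16 stack truncated to its first 12 convolutions
(stage depths 2/2/3/3, widths 64→512); pretrained weights can be loaded
from a local file (`load_encoder_weights()`), never downloaded.  A
literal VGG16 encoder forces 64-wide skip connections and is therefore
incompatible with a 32-channel final decoder, so the two presets are
first-class options rather than one being declared canonical; likewise
`bottleneck_factor = 4` enables a coarser 4×4-pooled bottom level as an
alternative to the standard 2×2.  `summary()` prints the layer table
and exact parameter count, which is a pure function of the
configuration.

Weights are initialised from a zero-mean Gaussian with variance `2/N`
(`N` = fan-in), biases zero.  Because no deep-learning runtime is
assumed, the forward and backward passes are implemented in compiled
code (im2col + BLAS matrix products) with hand-derived gradients; the
test suite checks them against central-difference numerical gradients.

## Training

The loss is `L = H − log J`: `H` the mean per-pixel cross-entropy and
`J` a smoothed, differentiable Jaccard index
`J_c = (Σ p_c y_c + ε)/(Σ p_c + Σ y_c − Σ p_c y_c + ε)` with ε = 1,
averaged over foreground classes present in the truth.  Background is
excluded from `J` by default — it dominates the pixel count and would
swamp the term — with a flag to include it.  The decomposition
`L = H − log J` holds exactly on every logged step.

Optimisation is adaptive moment estimation (β₁ = 0.9, β₂ = 0.999),
mini-batches of 4, learning rate 0.001 for base/single training and
0.0005 for fine-tuning, fixed (no schedule).  Augmentation applies the
same random rotation (±30°) and scaling (0.9–1.1) to image (bilinear)
and mask (nearest-neighbour, label-preserving), plus a gray-value shift
(±20) to the image only; ranges are configuration since the source
procedure does not state them.  Per-epoch validation mIoU is logged and
the best-validation weights are kept.  Fine-tuning trains all layers; a
`freeze_encoder` flag is available because freezing is a common
alternative, but training everything is the default: with all layers
free, the small labelled set can correct encoder features learned from
imperfect auto-labels, which is the point of the transfer step.

## The scaled replication

`run_transfer_protocol()` reproduces the three-regime experiment at a
size that runs on one CPU in a few minutes per seed
(`transfer_conditions()`): 64×64 scenes, RBC radius 3–4 px, macrophage
radius 8–11 px, mixed scenes with 6–10 RBCs and 1–2 macrophages; a tiny
U-Net (depth 3, widths 8/16/32/64); U-Single pretrained for 20 epochs on
200 auto-labelled single-kind images (100 RBC + 100 macrophage frames)
with 20 auto-labelled validation frames; U-Transfer fine-tuned for 10
epochs on 10 ground-truth-labelled mixed scenes; U-Base (optional)
trained for 20 epochs on 50 labelled mixed scenes; evaluation on 30
held-out mixed scenes by micro-averaged mIoU/FWIoU/Dice and per-class
counting accuracy with the default minimum-area counting (half the
smallest true cell area per class).  These sizes are the package's
replication conditions: large enough for the ordering of interest
(fine-tuning does not degrade the pretrained model) to be stable across
seeds, small enough for routine testing.  One full-scale relation does
not carry over: at this scale the supervised baseline sees only 50
labelled images against U-Single's 200 auto-labelled ones, and since
the synthetic task saturates for both, U-Base does not dominate
U-Single the way a 450-image baseline does at full scale.  Headline
numbers from the original full-scale experiment are not comparable in
any case because its dataset is private.

## Counting

`count_cells()` drops components below a per-class minimum area and
counts one cell per surviving 8-connected component.  Raising the
minimum area is provably non-increasing in every count.  An optional
`split_large` policy divides components larger than 1.5× a typical area
by that area — useful when merged clusters are expected — but defaults
off, since a component-equals-cell rule is the conservative reading of
area-based counting.  Reports flag border-touching components because
cells clipped by the frame are a known source of undercounting.
`count_accuracy()` reports predicted/true percentages, `NA` for classes
absent from the truth.

## Known limitations

* Adhesive macrophage pairs that the network predicts as one region are
  counted as one cell under the default policy; `split_large` mitigates
  but does not resolve this (no watershed is included by design).
* The classical pipeline assumes a single polarity (cells uniformly
  darker or lighter than the local background) and roughly convex
  cells; it does not handle hollow or overlapping cells.
* Metrics are micro-averaged over a split by summing confusion
  matrices; a per-image macro-average is available but the two differ
  on heterogeneous splits.
* Training determinism holds for a fixed BLAS; bit-level results can
  differ across numerically different BLAS builds.
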