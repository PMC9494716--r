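# cellseg

Semantic segmentation and per-class counting of mixed cell microscopy
images — red blood cells (RBCs) and macrophages — with a minimal
annotation budget.

Pixel-wise annotation is the bottleneck of CNN-based cell segmentation.
`cellseg` implements a label-economical training strategy: images that
contain only **one** kind of cell are labelled automatically by a
classical pipeline, a compact U-Net is pretrained on those auto-labels,
and the pretrained network is then fine-tuned on a small manually
labelled mixed-cell set.  Cells are finally counted from the predicted
mask by connected components after a minimum-area filter.

The package is aimed at method developers and at anyone who wants a
fully self-contained, CPU-only, reproducible testbed for this training
strategy: a seeded synthetic scene generator with exact ground truth
stands in for the (non-redistributable) microscopy data.

## What is inside

* **Auto-labeling** (`autolabel_image()`): Gaussian smoothing (3×3,
  σ = 0.8), adaptive thresholding with a Gaussian-weighted window
  (per-pixel threshold `T(x, y) = weighted mean − C`, strict
  inequality), border-following contour extraction of 8-connected
  components with small-area removal, morphological opening
  (`dst(x,y) = max/min over the kernel of src(x+x′, y+y′)`) to separate
  adhesive macrophages, and contour filling.
* **Synthetic scenes** (`generate_scene()`, `generate_dataset()`):
  seeded, bit-reproducible RBC/macrophage/mixed images with masks, true
  counts, sensor noise, illumination gradients and adhesive macrophage
  pairs.
* **U-Net** (`unet_config()`, `build_unet()`, `predict()`): size-configurable
  encoder–decoder with skip connections and nearest-neighbour
  upsampling; plain or truncated-VGG16 encoder; forward and backward
  passes implemented on BLAS with hand-derived gradients (no deep
  learning runtime required).
* **Training** (`train_unet()`, `finetune_unet()`): loss `L = H − log J`
  (cross-entropy plus soft Jaccard), Adam (β₁ = 0.9, β₂ = 0.999),
  batch 4, lr 0.001 (0.0005 for fine-tuning), rotation/scale/gray-value
  augmentation, per-epoch validation mIoU with best-checkpoint keeping.
* **Metrics** (`confusion()`, `miou()`, `fwiou()`, `dice()`,
  `eval_masks()`):
  `mIoU = (1/(k+1)) Σᵢ pᵢᵢ / (Σⱼ pᵢⱼ + Σⱼ pⱼᵢ − pᵢᵢ)` and its
  frequency-weighted variant from the pixel confusion matrix, Jaccard
  and Dice (`D = 2J/(1+J)`).
* **Counting** (`components()`, `count_cells()`, `count_accuracy()`):
  per-class 8-connected components, minimum-area false-positive
  removal, optional area-based splitting of oversized components,
  accuracy as predicted/true percentages.
* **Protocol** (`run_transfer_protocol()`): the three-regime experiment
  (U-Base / U-Single / U-Transfer) at desk scale on synthetic data.
* **CLI** (`inst/cli/cellseg.R`):
  `synth | autolabel | train | finetune | predict | count | eval`.

## Worked example

```r
library(cellseg)

cfg <- synth_config()                       # 256x256 default conditions
scene <- generate_scene(cfg, "rbc", seed = 7)
print(scene)
#> synthetic rbc scene: 256 x 256 px, 17 RBC(s), 0 macrophage(s)

# auto-generate a training mask for this single-kind image
label <- autolabel_image(scene$image,
                         autolabel_config_for(cfg, "rbc"), class_value = 1)
jaccard(scene$mask == 1, label == 1)
#> [1] 0.9962

# count cells in a mask with the matched minimum areas
mixed <- generate_scene(cfg, "mixed", seed = 7)
report <- count_cells(mixed$mask, min_areas_for(cfg))
print(report)
#> cell counts (min area 1: 25, 2: 157):
#>   class 1: 17
#>   class 2: 3
count_accuracy(report, mixed$counts)
#>   1   2
#> 100 100
```

The IoU of 0.996 says the automatically generated mask agrees almost
pixel-perfectly with the generator's ground truth; the count report
recovers all 17 RBCs and 3 macrophages, i.e. 100% counting accuracy for
both classes.

Training the tiny network end-to-end (a few minutes on one CPU):

```r
r <- run_transfer_protocol(seed = 1)
r$single$miou     # test mIoU after pretraining on auto-labels only
r$transfer$miou   # test mIoU after fine-tuning on 10 labelled scenes
r$count_accuracy  # per-class counting accuracy of the fine-tuned model
```

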