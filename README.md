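# spotlight3d

Foreground-aware training and evaluation for 3D virtual staining of
fluorescence volumes from transmitted-light microscopy input.

## The problem

Virtual staining (in-silico labeling) models predict a fluorescence channel
from a label-free volume with an image-to-image regression network. In 3D
nuclear imaging the background dominates the voxel count and carries only
noise, offset and optical artifacts — most prominently the axially
elongated "halo" of the anisotropic point-spread function. A network
trained with a plain pixel-wise loss learns to reproduce exactly that
background, and its predictions segment as badly as the raw fluorescence
data. This package is for computational microscopists who want a training
objective that concentrates supervision on the biology, plus the full
evaluation stack needed to demonstrate that it worked.

## The objective

A binary foreground mask `M` is derived from the *target* volume `Y` by
Otsu's threshold `T` (`M_ijk = 1` iff `Y_ijk >= T`). Training minimizes

```
L = lambda * L_MMSE + (1 - lambda) * L_Dice

L_MMSE = (1 / sum(M)) * sum_ijk M_ijk (Y_ijk - Yhat_ijk)^2
L_Dice = 1 - 2 sum(sigma_k(Yhat) * M) / (sum(sigma_k(Yhat)) + sum(M) + eps)
```

where `sigma_k(x) = (x - kx) / (k - 2k|x| + 1)` is the normalized tunable
sigmoid on `[-1, 1]` — `k = 0` is the identity, `k -> -1` approaches a hard
step — applied to the prediction after recentring about the mask threshold.
Masked MSE supervises foreground intensity; the Dice term pushes the
*shape* of the soft-thresholded prediction toward the mask and drives
background voxels to zero. All gradients are closed-form; the small 3D
encoder-decoder backbone ships with its own reverse-mode pass (Rcpp), so
training runs on a plain CPU with no deep-learning framework.

Alongside the losses the package provides: a seeded generator of paired
synthetic nucleus volumes with instance labels and an axial-elongation
artifact; whole-image and foreground-restricted PSNR and 3D SSIM; Fourier
shell correlation resolution estimates; watershed instance segmentation
(exact 3D Euclidean distance transform + seeded priority flood) scored by
`AP = TP/(TP+FP+FN)` at multiple IoU levels; intensity-threshold sweeps;
and per-nucleus morphological profiles compared by cosine distance.

## Worked example

```r
library(spotlight3d)

s <- generate_sample(synth_config(seed = 7))
s
#> synthetic_sample: 64x64x64, 6 nuclei placed, seed 7

tn <- normalize_volume(s$target_volume)$data
set.seed(1)
pred <- array(pmin(1, pmax(0, tn + rnorm(length(tn), 0, 0.08))), dim(tn))

spotlight_loss(tn, pred)
#> spotlight loss: 0.108893 (mmse 0.00635003, dice 0.519067; mask T = 0.3594)

metrics_report(tn, pred)
#>  psnr_whole  psnr_fg ssim3d_whole ssim3d_fg frc_resolution mask_fraction
#>    22.50023 21.97224     0.472673 0.9155311              2    0.03251266

lab <- watershed_segment(tn)
average_precision(s$labels, lab)
#>   iou_threshold TP FP FN AP
#> 1           0.5  6  0  0  1
#> 2           0.6  6  0  0  1
#> 3           0.7  6  0  0  1
#> 4           0.8  6  0  0  1
#> 5           0.9  0  6  6  0
#> mean AP: 0.8000
```

Reading the numbers: the Otsu mask covers ~3% of voxels (`mask_fraction`),
so the whole-image PSNR of a noisy prediction is dominated by background
while the foreground-restricted column isolates fidelity where the nuclei
are. The Dice component (0.52) is large here because additive noise pushes
many background voxels across the soft threshold — exactly the signal the
combined loss penalizes during training. Watershed on the target recovers
all 6 planted nuclei at IoU up to 0.8 against the pre-blur supports; at
0.9 the blur halo costs the match, which is the artifact the
foreground-aware objective is designed to suppress in predictions.

Training and comparing both objectives end-to-end:

```r
study <- method_comparison_study(base_seed = 1)   # ~10 min on one core
study
```

This trains seed-matched backbone pairs (identical data, splits and
schedule; only the loss differs) and reports, per seed: foreground PSNR,
background mean absolute intensity, watershed AP@0.5 against the true
instance labels, FSC resolution, profile cosine distance, and the AP@0.5
spread under an intensity-threshold sweep.

A thin command-line front end over the same functions is installed at
`inst/cli/spotlight.R` (`simulate`, `train`, `predict`, `evaluate`,
`segment`, `sweep`, `profile`, `compare`).

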