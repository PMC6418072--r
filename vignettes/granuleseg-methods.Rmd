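---
title: "Methods: segmenting and quantifying insulin granules in EM images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting and quantifying insulin granules in EM images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Insulin is stored in large dense-core vesicles (LDCVs) of pancreatic beta
cells. Under the electron microscope a granule appears as a dark,
electron-dense core separated from its limiting membrane by a bright halo,
with diameters of roughly 100–800 nm. Counting and measuring thousands of
granules per cell by hand is impractical, and granules occupy only a small
fraction of each micrograph, so naive per-pixel classifiers can score high
pixel accuracy while missing every granule. `granuleseg` implements a full
pipeline from raw 2-D micrograph to per-granule morphometry:

1. global histogram equalization (`equalize_histogram()`),
2. semantic segmentation by a multi-branch fully convolutional network
   (`build_mfcn()`, `mfcn_train()`, `predict_mask()`),
3. watershed instance segmentation of the binary map
   (`watershed_instances()`, `filter_instances()`),
4. morphometry and population statistics (`measure_granules()`,
   `granule_density()`, `distance_profile()`, `compare_groups()`),
5. evaluation metrics (`pixel_metrics()`, `match_instances()`).

Because no annotated EM data ship with the package, a seeded synthetic
generator (`scene_spec()`, `generate_scene()`) produces FIB-SEM-like
micrographs with complete ground truth, and every stage is tested against
it.

## Pre-processing

Histogram equalization uses the classical CDF stretch
$h(v) = \mathrm{round}\!\left((cdf(v) - cdf_{\min})/(N - cdf_{\min})\cdot 255\right)$,
applied globally and per image. The mapping is monotone, so pixel rank
order is preserved; a constant image is returned unchanged with a warning.
Adaptive variants (CLAHE) were deliberately not used: a single global
correction suffices to homogenise the smooth illumination gradients seen in
FIB-SEM data, and the same deterministic transform can then be applied
identically at training and prediction time.

## Network architecture

The MFCN consists of three modules:

* **Multi-scale inception.** The input passes through parallel stride-2
  convolutions with kernels 3×3, 5×5 and 7×7. Each kernel seeds one branch,
  so the branches start from features of different granularity; larger
  kernels are more robust to EM noise.
* **Multi-branch sampling.** Each branch is an encoder–decoder with total
  down/up-sampling 4×, 8× or 16× (including the inception stride).
  Down-sampling is by strided 3×3 convolution, up-sampling by 2×2 stride-2
  transposed convolution, each followed by batch normalisation and a
  rectifier. There are no skip connections inside a branch. Each branch
  ends in a 2-channel score map at full resolution.
* **Multi-scale ensemble.** The branch score maps are sliced per class and
  concatenated (all background slices, then all granule slices) and fused
  by a 1×1 convolution, followed by a channel softmax. Under a 1×1
  convolution the slicing order is equivalent to a plain concatenation up
  to a channel permutation; the sliced form is implemented.

Channel widths follow `base_channels × channel_growth^level` (defaults 16
and 2). Branches with larger factors therefore see strictly larger
receptive fields, which `mfcn_receptive_field()` verifies by
gradient-support probing with the rectifier linearised (training-mode batch
norm couples all pixels through the batch statistics, so probing uses the
eval-mode affine form).

Several training details are design choices of this package: the loss is
pixel-wise 2-class cross-entropy with inverse-frequency class weighting
(granules are a small minority of pixels, so the unweighted loss has a
trivial all-background optimum nearby); the optimiser is Adam at learning
rate 1e-3 with batch size 4; initialisation is He-scaled; one master seed
fans out to initialisation and shuffling, making training bit-reproducible
on a fixed machine. The transposed convolution uses kernel 2 with stride 2
so output blocks partition the raster exactly (no checkerboard overlap).
Inputs not divisible by the largest branch factor are reflect-padded and
the output cropped back. A threshold tie goes to background (strict
inequality). The layers themselves (im2col/GEMM convolutions, fused
batch-norm/rectifier kernels, full backpropagation) are implemented in the
package in C++, which keeps a desk-scale model (≈186k parameters)
trainable on one CPU core in minutes.

## Watershed instance segmentation

The binary map is split into instances by: Euclidean distance transform of
the foreground; Gaussian smoothing (σ = 1 px by default — digital discs
have flat distance plateaus that smoothing turns into unique peaks); seed
selection at 3×3 local maxima, greedily accepted in decreasing height with
a minimum mutual separation; and marker-based priority-flood watershed on
the distance surface restricted to the foreground, 4-connected. Ridge
pixels are flooded from the basin that reaches them with the larger
distance value, so the union of instances equals the input foreground
exactly and area measurements are unbiased. The default seed separation is
the minimum granule diameter (100 nm) in pixels — the one free parameter is
tied to the biological size prior, as is the instance area gate
(100–800 nm diameters converted to pixel areas).

4-connectivity is used throughout to prevent diagonal leakage between
touching granules. If suppression leaves a foreground component with no
seed (a sliver next to a much taller neighbour), the component is labeled
as its own instance rather than dropped, preserving pixel conservation.

## Morphometry

Per instance: area = pixel count × (pixel size)², equivalent radius
$\sqrt{A/\pi}$, mean gray level, and round coefficient $4\pi A/P^2$ (the
isoperimetric ratio: 1 for a circle, lower for rods and irregular shapes).
The perimeter estimator matters here: raw pixel-edge counts bias the round
coefficient of digital circles to ≈0.78, and polygons through boundary
pixel centres run about half a pixel inside the true contour. The package
instead measures the sub-pixel 0.5-level contour (mid-crack polygon)
smoothed by a cyclic 5-point moving average; on digital discs this gives
round coefficients between 1.05 (radius 5 px) and 0.99 (radius 40 px),
restoring the circle → 1 limit. Below ~4 px radius discretization
dominates and the ratio can exceed 1.1; the area gate excludes such
fragments at the default pixel size.

Membrane distance is measured from the granule's outer boundary (not its
centroid) to the nearest segment of the membrane polyline: the ~40 nm
docking criterion is a membrane-to-membrane gap, far smaller than a granule
radius. Distance profiles bin distances in `[k·w, (k+1)·w)` up to a
maximum (a distance exactly at the maximum falls in the last bin) and
report relative frequencies over the granules within range. Densities are
computed per cell (granules per µm² of cytoplasm, nucleus excluded) and
averaged with the s.e.m. taken across cells, matching per-cell reporting;
with a single cell the s.e.m. is reported as 0 and flagged. Group
comparisons expose a two-sided equal-variance Student's t-test for means
and a two-sample Kolmogorov–Smirnov test for distributions. Dense-core
radii are measured on the core instance map with the same equivalent-radius
formula, cores being matched to parent granules by maximal pixel overlap.

## Synthetic scenes

`generate_scene()` renders: a smooth cell blob (radial harmonics, ~65 % of
the frame) whose boundary is the plasma-membrane polyline; an optional dark
nucleus-like blob (the classic false-positive trap for encoder–decoder
segmenters on beta-cell EM data); granules as anti-aliased bright halo
annuli around dark cores (discs, or capsules of aspect 2–4 for a
configurable rod fraction); a multiplicative planar illumination ramp
(optionally a radial vignette); and additive Gaussian noise, clipped to
8 bits. Granule counts are Poisson with mean density × cytoplasm area;
centres are rejection-sampled so granules lie fully inside the cytoplasm
and pairwise interior overlap stays ≤ 20 % of the smaller disc — touching
granules are produced on purpose so the watershed splitter is exercised on
its hard case. If more than 5 % of the drawn count cannot be placed, the
generator raises an error rather than silently under-placing.

Defaults (chosen once as plausible FIB-SEM-like conditions, not calibrated
to any real acquisition): 128×128 px at 20 nm/px, density 1.5/µm², radii
60–240 nm, core/granule radius ratio 0.55, rod fraction 0.2, gray levels
core 40 < cytoplasm 120 < halo 200, illumination amplitude 0.15, noise σ 8,
nucleus present. Intensities must satisfy the core < cytoplasm < halo
ordering of real LDCVs. What the generator does **not** emulate: 3-D
structure and section-position effects, correlated (structured) EM noise,
charging artefacts, organelles other than the nucleus distractor, and
real annotation noise. Passing tests on these scenes therefore demonstrate
the internal consistency and calibration of the pipeline — recovery of
known geometry, counts and densities — not performance on real micrographs.

## Evaluation

Pixel metrics follow the standard confusion-matrix definitions (pixel
accuracy, mean per-class accuracy, mean IU), with absent classes excluded
from the means. Object-level detection uses greedy one-to-one matching in
descending IoU with a 0.5 default threshold; unmatched predictions are
false positives, unmatched truths false negatives. Object-level true
negatives are reported as not applicable — there is no countable set of
"true negative objects"; the pixel-level confusion matrix carries the TN
count. Undefined precision (no predictions at all) is reported as 0 with
an explicit flag so scores aggregate stably across scenes.

## Problem sizes and numerical choices

The packaged experiments run at desk scale, chosen so the full suite
completes in minutes on one CPU: the end-to-end check trains the default
three-branch network (base 16 channels, ≈186k parameters) with seed 0 on
100 synthetic 128×128 scenes for 8 epochs and evaluates 20 held-out scenes
(mean IU ≈ 0.90, detection precision ≈ 0.93–0.95, nucleus leakage well
under 1 % of foreground pixels in our runs); watershed recovery uses 100
noise-free scenes; density calibration uses 200 scenes per cohort at 1.03
and 2.3 granules/µm². Batch-norm uses ε = 1e-5 and momentum 0.1; softmax
is computed with max-subtraction; the cross-entropy adds 1e-12 inside the
logarithm; probability maps sum to 1 within 1e-5 per pixel. Degenerate
inputs are handled explicitly: constant images (equalization), empty masks
(watershed), empty prediction sets (precision), single cells (s.e.m.), and
a single-branch single-kernel network is a valid degenerate configuration
that reduces to a plain FCN.

## Known limitations

* Morphometry is strictly 2-D: radii are section radii, not sphere radii
  reconstructed from volumes.
* The synthetic generator's realism limits, listed above, bound what the
  tests can demonstrate about real EM data.
* Training hyperparameters (loss, optimiser, augmentation, widths, depths)
  are declared package defaults; transferring to real micrographs will
  likely require retuning and real annotations.
* The CPU implementation targets desk-scale models; it is not a
  general-purpose deep-learning framework.
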