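# granuleseg

Automatic segmentation and morphometry of insulin secretory granules
(large dense-core vesicles, LDCVs) in 2-D electron micrographs of
pancreatic beta cells.

Under EM, an insulin granule is a dark electron-dense core separated from
its limiting membrane by a bright halo, 100–800 nm in diameter. Counting
and measuring thousands of them per cell by hand is impractical, and
because granules occupy only a small fraction of each image, naive
classifiers can reach high pixel accuracy while missing every granule.
`granuleseg` is for microscopists and image analysts who need per-granule
numbers — radius, shape, gray level, distance to the plasma membrane,
density per µm² of cytoplasm — from raw micrographs, with every stage
testable against synthetic ground truth.

## The pipeline

1. **Pre-processing** — global histogram equalization,
   `h(v) = round((cdf(v) − cdf_min)/(N − cdf_min) · 255)`, homogenises
   uneven illumination.
2. **Semantic segmentation** — a multi-branch fully convolutional network
   (MFCN): a multi-scale inception front end (parallel 3×3 / 5×5 / 7×7
   stride-2 convolutions, one per branch), three encoder–decoder branches
   with 4× / 8× / 16× total down/up-sampling and no internal skip
   connections, and an ensemble head that slices the branch score maps per
   class, concatenates them and fuses with a 1×1 convolution before a
   softmax. Layers, class-weighted cross-entropy loss, Adam and full
   backpropagation are implemented in the package (C++ under the hood), so
   a desk-scale model trains on one CPU core in minutes.
3. **Instance segmentation** — marker-based watershed on the smoothed
   Euclidean distance transform of the binary map, with seed separation
   tied to the 100 nm minimum granule diameter, followed by an area gate
   from the same size prior.
4. **Morphometry** — per granule: area, sub-pixel contour perimeter,
   equivalent radius √(A/π), round coefficient 4πA/P² (1 for a circle),
   mean gray, dense-core radius, boundary-to-membrane distance; per
   population: density mean ± s.e.m. across cells, binned
   membrane-distance profiles, Student's t and Kolmogorov–Smirnov tests.
5. **Evaluation** — pixel accuracy, mean accuracy, mean IU, and one-to-one
   greedy IoU matching for object-level TP/FP/FN and precision.

A seeded synthetic generator (`generate_scene()`) renders FIB-SEM-like
beta-cell scenes — halo-and-core granules (with rod-shaped cores at a
configurable fraction), a dark nucleus-like distractor, illumination
gradient, noise — with complete ground truth, so the whole pipeline is
exercisable without annotated EM data.

## Worked example

```r
library(granuleseg)

# Train the default three-branch network on a synthetic cohort
# (~2 minutes on one CPU core)
cfg <- run_config(epochs = 8, seed = 0)
scenes <- simulate_scenes(104, scene_spec(), seed = 1)
state <- train_on_scenes(scenes[1:100], cfg)
glance(state)
#> # A tibble: 1 × 5
#>   steps epochs first_epoch_loss final_epoch_loss final_loss
#>   <int>  <int>            <dbl>            <dbl>      <dbl>
#> 1   200      8            0.520           0.0338     0.0331

# Segment a held-out scene end to end and measure its granules
scene <- scenes[[104]]
instances <- segment_image(state$network, scene$image, cfg)
granules <- measure_granules(instances, scene$image,
                             membrane = scene$membrane_polyline)
dplyr::select(granules, id, equiv_radius_nm, round_coefficient,
              mean_gray, membrane_distance_nm)
#> # A tibble: 2 × 5
#>      id equiv_radius_nm round_coefficient mean_gray membrane_distance_nm
#>   <int>           <dbl>             <dbl>     <dbl>                <dbl>
#> 1     1            165.             0.902      148.                 457.
#> 2     2            145.             0.912      146.                 115.

# How well did we do against the ground truth?
evaluate_scenes(state$network, scenes[101:104], cfg)[, c("scene", "mean_iu",
  "precision", "recall", "nucleus_leakage")]
#> # A tibble: 4 × 5
#>   scene mean_iu precision recall nucleus_leakage
#>   <int>   <dbl>     <dbl>  <dbl>           <dbl>
#> 1     1   0.888         1    0.9         0
#> 2     2   0.878         1    1           0
#> 3     3   0.906         1    1           0.00405
#> 4     4   0.806         1    1           0
```

The two granules found in the held-out scene are near-circular
(round coefficient ≈ 0.9), with radii of 145–165 nm, and one sits 115 nm
from the plasma membrane — the kind of per-granule record used to build
radius distributions, round-coefficient distributions and membrane-distance
profiles across cells (`granule_density()`, `distance_profile()`,
`compare_groups()`). On held-out scenes the trained network reaches mean
IU around 0.9 with object-level precision near 1, and essentially no
predicted foreground leaks into the dark nucleus-like distractor.

`write_granule_table()` exports the measurements as a flat CSV (0-based
pixel centroids, `centroid_x_px` = column), and `write_boundaries()` a JSON
sidecar of boundary polygons. `autoplot()` methods display scenes and
training traces; `plot_instances()` and `plot_distance_profile()` the
results.

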