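# octasens

Sensitivity of OCT angiography vasculature metrics to simulated capillary
loss.

## What this package is for

En-face OCT angiography (OCT-A) of the parafoveal retina is quantified with
scalar metrics — vessel density, foveal avascular zone (FAZ) area,
parafoveal intercapillary area (PICA) statistics, vessel perimeter and
complexity indices (VPI, VCI), and box-counting fractal dimension (FD).
These metrics respond very differently when capillaries drop out.
`octasens` is for researchers choosing metrics for OCT-A studies: it
quantifies, by simulation, how much capillary loss each metric needs before
it reliably leaves the normal range.

The framework:

1. **Segment** a standardized angiogram (2380 µm field, 304 px, upsampled
   6× to a 1824×1824 analysis raster) into a binary vessel image, an
   arteriole/venule mask, and 1-px skeletons.
2. **Decompose** the capillary skeleton into a segment graph: pixel chains
   between branch/end points.
3. **Simulate** randomized capillary loss: for each intended level *L* ∈
   {1…50}% and each of *n* iterations, remove a random permutation of
   segments until the removed pixel fraction just exceeds *L*, rebuild the
   binary image (re-dilate the remaining skeleton by a radius-5 disk, OR
   the large-vessel mask back), and compute all 13 metrics.
4. **Score**: the cohort's baseline metrics define a normative mean ± 2 SD
   band; each specimen's trajectory is ratio-normalized to the cohort mean
   and z-scored. A metric's sensitivity is the loss level at which 80% of
   iterations fall outside the band:

   sensitivity = min { L : #{ |z(L, iter)| > 2 } ≥ 0.8 · n },

   linearly interpolated between grid levels. Cohort-averaged sensitivities
   rank the 13 metrics into tiers.

Because no raw study images are distributable, the package ships a seeded
synthetic-cohort generator (`generate_network()`, `generate_cohort()`)
producing angiogram-like images with exact ground truth (binary
vasculature, large-vessel mask, FAZ region), calibrated so a default cohort
matches the published normative summary (FAZ area 0.272 ± 0.102 mm²,
vessel density ≈ 48.9%).

## Worked example

```r
library(octasens)

specimen <- generate_network(network_params(), seed = 1)
specimen
#> <synthetic_specimen> synth_000001: 1824 px field, FAZ 0.272 mm^2,
#>   vessel density 48.6%, seed 1

seg     <- as_vessel_segmentation(specimen)   # ground-truth segmentation
metrics <- compute_all(seg$binary, seg$center_xy, seg$px_area_mm2)
metrics
#> <octa_metrics>
#>       faz_area_mm2     vessel_density                vci                vpi
#>          2.720e-01          4.857e-01          2.727e+03          8.993e-02
#>                 fd      pica_mean_mm2       pica_sum_mm2    pica_regularity
#>          1.852e+00          1.293e-03          2.911e+00          2.260e-01
#>        pica_sd_mm2   nf_pica_mean_mm2    nf_pica_sum_mm2 nf_pica_regularity
#>          5.722e-03          1.173e-03          2.639e+00          2.915e+00
#>     nf_pica_sd_mm2
#>          4.023e-04
```

The FAZ area is the generator's target (0.272 mm²); vessel density, FD,
VPI and the PICA means/sums sit close to the published normative values
for healthy parafoveal full-slab images (e.g. mean PICA 0.0013 mm², summed
PICA 2.9 mm², FD 1.86, VPI 0.094).

Simulate one 10%-loss trial and recompute:

```r
graph <- skeleton_to_graph(seg$capillary_skeleton)
graph
#> <skeleton_graph> 9510 segments, 46695 node pixels, 158266 skeleton px

trial <- remove_segments_until(graph, intended_pct = 10, seed = 7)
#> intended 10% -> removed 1349 segments, actual loss 10.00%

lost  <- rebuild_binary(seg$full_skeleton, trial, seg$large_mask)
after <- compute_all(lost, seg$center_xy, seg$px_area_mm2)
round(rbind(baseline = metrics, lost10 = after), 4)[, c(1, 2, 4, 5)]
#>          faz_area_mm2 vessel_density    vpi     fd
#> baseline       0.2720         0.4857 0.0899 1.8522
#> lost10         0.2738         0.4512 0.0857 1.8396
```

Removing 10% of capillary segments lowers vessel density by ~3.5
percentage points while the FAZ barely grows — exactly the differential
responsiveness the sensitivity analysis quantifies. The full cohort
analysis is one call:

```r
cohort <- generate_cohort(cohort_params(n_specimens = 20))
fit <- octa_sensitivity(cohort, sweep = sweep_config(n_iter = 100))
summary(fit)      # per-metric mean sensitivity, ranks, tiers
plot(fit)         # outside-band fraction vs intended loss, per metric
```

`run_pipeline(validate_config("cfg.yaml"))` runs the same analysis end to
end (synthetic or image-directory input) and writes CSV/JSON tables plus a
hashed run manifest; `inst/scripts/octasens.R` wraps it for the shell.

## Package layout

- `R/synthetic.R` — seeded synthetic specimen/cohort generator
- `R/standardize.R` — axial-length rescaling and common-field cropping
- `R/segmentation.R` — preprocessing and vessel segmentation stages
- `R/simulator.R` — skeleton graph, randomized segment removal, rebuild
- `R/metrics.R` — the 13-metric battery
- `R/sensitivity.R` — normative band, z-scoring, sensitivities, tiers
- `R/pipeline.R` — config validation and end-to-end orchestration
- `src/core.cpp` — compiled raster primitives (resampling, morphology with
  exact Euclidean disks, run-based connected components, thinning, box
  counting, skeleton-graph extraction, fused per-trial rebuild+metrics)
- `vignettes/octasens-methods.Rmd` — the model, conventions and design
  choices in detail
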