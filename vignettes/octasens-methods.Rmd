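---
title: "Ranking OCT-A vasculature metrics by their sensitivity to capillary loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking OCT-A vasculature metrics by their sensitivity to capillary loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octasens)
```

## The question

En-face OCT angiography (OCT-A) images of the parafoveal capillary plexus are
summarized by a growing family of scalar metrics: vessel density, foveal
avascular zone (FAZ) area, parafoveal intercapillary area (PICA) statistics,
perimeter- and complexity-based indices, and the box-counting fractal
dimension. When capillaries drop out — through disease, intermittent
perfusion, or degraded image quality — these metrics respond at very
different rates. `octasens` implements a simulation framework that
quantifies each metric's sensitivity: the smallest fraction of randomly
removed capillary segments at which the metric reliably leaves the normal
range of a healthy cohort.

The procedure, per specimen:

1. segment the standardized angiogram into a binary vessel image, a
   large-vessel (arteriole/venule) mask, and 1-px skeletons;
2. decompose the capillary skeleton into a segment graph (pixel chains
   between branch/end points);
3. for each intended loss level \(L \in \{1, \dots, 50\}\%\) and each of
   `n_iter` iterations, remove a random permutation of segments until the
   removed pixel fraction just exceeds \(L\), rebuild the binary image
   (re-dilate the remaining skeleton, restore the large-vessel mask), and
   compute all 13 metrics;
4. ratio-normalize each specimen's trajectory to the cohort baseline mean,
   z-score it against the cohort baseline SD, and report the loss level at
   which 80% of iterations fall outside the mean ± 2 SD normative band.

The cohort-averaged sensitivities rank the metrics and group them into
tiers (most sensitive: tier 1; most robust: tier 3).

## The thirteen metrics

All metrics are computed on an analysis-scale binary image (canonically
1824 × 1824 px covering 2380 µm, i.e. upsampled 6× from the 304-px
standardized image):

* **Vessel density** — foreground fraction of the raster.
* **FAZ area** — area (mm²) of the background component containing the
  center pixel (912, 912), provided it is among the 10 largest nonperfused
  regions; otherwise the nearest background component is used with a
  warning.
* **PICA mean / sum / SD / regularity** — statistics of the background
  component areas at least 51 px² large (smaller regions are resampling
  debris), computed once including and once excluding the FAZ component
  (`nf_` prefix). Regularity is mean/SD. The SD uses the sample (n−1)
  convention by default; the population convention is a `pica_config()`
  option because published implementations differ.
* **VPI** — vessel perimeter pixels (8-connectivity boundary; the image
  border counts as background) divided by the raster size.
* **VCI** — perimeter²/(4π · vessel area), normalized by 1.6169 so a filled
  circle inscribed in the frame scores 1. `vci_norm_constant()` recomputes
  this constant from a rasterized disk (membership rule
  \((x-c)^2+(y-c)^2 \le r^2\), center pixel (912, 912), r = 912), giving
  1.6185 — the small difference from the published constant reflects the
  rasterization convention and is well inside the tolerance of every check
  that uses it.
* **FD** — box-counting dimension over dyadic box sizes \(1, 2, 4, \dots\)
  up to the shorter image side, as minus the least-squares slope of
  \(\log N(s)\) on \(\log s\). A global fit is used rather than averaged
  local slopes; both appear in the literature and the global fit is the
  reproducible choice for a fixed size grid.

Two digital-topology conventions matter and are pinned (and configurable):
background regions are 4-connected while vessels are 8-connected, so
intercapillary areas cannot leak diagonally through vessel walls; and
structuring elements are exact Euclidean disks
\(\{(dx,dy): dx^2+dy^2 \le r^2\}\).

## Segmentation pipeline

`segment_vessels()` reproduces a fixed, operator-free pipeline:

1. **Preprocessing** (`preprocess_intensity()`): 1% contrast stretch;
   background estimation by grayscale opening with a disk of radius 15 px
   and subtraction; a second stretch; 6× bicubic upsampling; a dual
   threshold (below 20 → 0, above 35 → 255, intermediate values pass
   through); optionally a small averaging filter. The stretched image
   *before* the dual threshold is kept alongside, because the large-vessel
   stages operate on it.
2. **Small capillaries**: local-mean adaptive threshold (window 15),
   subtraction of the foreground perimeter, inversion–median–inversion
   denoising, skeletonization, removal of components of ≤ 10 px, one
   endpoint-pruning pass, deletion of isolated pixels, an intensity floor of
   30, then dilation by a disk of radius 5 (capillary caliber 11 px).
3. **Large vessels**: adaptive threshold at window 30 on the stretched
   image, removal of components under 3000 px, intensity mask > 30.
4. **Combination and FAZ cleanup**: union of the two segmentations; then
   isolated foreground blobs (< 200 px, touching only FAZ background) inside
   the center-containing background component are deleted — a deterministic
   replacement for interactive noise removal, so that runs are reproducible.
5. **Arteriole/venule mask**: Otsu binarization of the stretched image,
   removal of components ≤ 400 px, dilation by radius 6.
6. **Skeletons**: the full skeleton thins the cleaned binary image; the
   capillary skeleton is the full skeleton minus mask pixels. Masking the
   skeleton (rather than re-thinning the masked binary) guarantees that
   every removable segment pixel exists in the full skeleton, which the
   rebuild step requires; the two orders differ only at mask boundaries.

The adaptive thresholds use a local *mean* over a square window with a
constant offset (default 0) — the offset is exposed in
`segmentation_config()` because reference implementations take one without
documenting a value. The median filter is 3 × 3 and spur pruning is a
single pass; both are configurable for the same reason.

## Loss simulation

`skeleton_to_graph()` classifies skeleton pixels by their number of
foreground 8-neighbors: pixels with ≠ 2 neighbors are nodes; maximal
degree-2 chains between nodes are segments; isolated cycles get a
designated break node. Node pixels are never removed, so junction geometry
survives any removal and segments stay pixel-disjoint. The loss denominator
is the full capillary-skeleton pixel count (nodes included); consequently a
nominal 100% loss terminates by exhausting the segments at slightly less
than 100% measured loss.

"Just exceeded" is read strictly: segments are removed in seeded random
permutation order until the removed fraction is strictly greater than the
intended level (ties continue; a `>=` variant is one flag away). This gives
the characteristic small positive overshoot whose mean is essentially
independent of the intended level. Each trial draws its permutation from an
independent substream seeded by (master seed, specimen, level, iteration),
so any single trial can be reproduced in isolation.

`rebuild_binary()` subtracts the removed pixels from the *unmasked* full
skeleton, re-dilates with the radius-5 disk, and ORs the large-vessel mask
back in, so arterioles/venules never shrink. The 0%-loss rebuild is the
canonical baseline image for metric computation at every level, making 0%
the simulator's identity case.

## Normative band and sensitivity

Baselines from all specimens define per-metric means and SDs (sample
convention). Each specimen's trial values are multiplied by
(cohort mean / specimen baseline), so every specimen starts exactly at the
cohort mean — computed as `(value / baseline) * mean` so the anchoring is
exact in floating point. Trials are z-scored with the cohort SD; "outside"
is strict (|z| > 2; boundary equality counts inside). The sensitivity is
the 80% crossing of the outside-fraction profile, linearly interpolated
between adjacent grid levels (reporting the first integer level instead is
a flag); profiles that never reach 80% by the maximum level are censored
and reported as such. Cohort means average non-censored specimens only, and
the achieving count n/N is always reported alongside. Multiplicative
normalization was chosen over an additive shift (both anchor the baseline
exactly; both are implemented) because the metrics are ratio-scaled
quantities; z-based sensitivities are invariant to any cohort-wide
rescaling of a metric either way.

Tier labels use thresholds on the cohort mean sensitivity (< 12% → tier 1,
< 20% → tier 2, otherwise tier 3), which reproduce the canonical grouping:
FAZ-excluded PICA dispersion metrics are the most sensitive; vessel
density, VPI and FAZ-inclusive PICA sums occupy the middle; FD, VCI, FAZ
area and FAZ-inclusive PICA regularity are the most robust.

## The synthetic cohort generator

No public OCT-A image set accompanies the protocol, so `generate_network()`
produces specimens with known ground truth:

* **Capillary mesh**: boundaries of the nearest-site cells of a relaxed
  (jittered-grid) point process, rasterized as 1-px chains and dilated to an
  11-px caliber. Cell-boundary networks yield simply connected polygonal
  intercapillary regions like real PICA regions. The default seed density
  (410 points/mm²) was calibrated once so the default geometry yields a
  truth vessel density near 48.9%, matching the normative cohort mean; the
  resulting baseline PICA summary statistics land close to the normative
  table without further tuning.
* **FAZ**: an additively weighted central cell whose boundary capillaries
  form a closed ring. After a first rasterization the imposed radius is
  corrected by one root-finding step so the measured enclosed area matches
  the target — FAZ areas track their targets to a few percent.
* **Arterioles/venules**: a few thick, smooth Bezier arcs entering from the
  field border and bending around the center, rendered brighter than the
  capillaries (stronger decorrelation signal), which is what lets the
  Otsu-based mask stage isolate them, as it does on real angiograms.
* **Rendering**: blurred truth raster with background/vessel intensity
  offsets, multiplicative speckle clipped to [0, 255], and antialiased
  bicubic downsampling to the 304-px acquisition scale.
* **Cohort draws**: FAZ area ~ N(0.272, 0.102²) mm² (truncated positive),
  mesh density with an 8% coefficient of variation (giving a baseline
  vessel-density spread of about 2 percentage points), axial length from a
  normal truncated below at 21.39 mm so the cohort minimum coincides with
  the standardization anchor.

What the generator deliberately does not emulate: OCT-A speckle physics and
flow decorrelation, projection artifacts, multi-layer plexuses, vessel
tortuosity and caliber heterogeneity, and pathology-specific (sectoral)
dropout patterns. Tests passing on synthetic cohorts therefore validate the
pipeline's mechanics and the relative ordering of metric sensitivities, not
absolute sensitivities on any particular device's images.

## Numerical and design choices

* Bicubic (Keys, a = −0.5) resampling everywhere, with kernel widening for
  antialiased downsampling; dimensions round up on axial rescaling so no
  field is lost at the margins.
* The published center coordinate convention is 1-based; `(912, 912)` is
  used as given, and the inscribed-circle constant is computed at that
  center.
* Component-size rules follow the stated inclusive/exclusive boundaries
  exactly: skeleton objects ≤ 10 px removed, large-vessel components
  < 3000 px removed, mask components ≤ 400 px removed, intercapillary
  regions < 51 px² excluded.
* Degenerate inputs are defined rather than fatal: constant-intensity
  images pass preprocessing with a warning; an all-foreground image yields
  density 1 with FAZ/PICA undefined (`NA`); zero-SD PICA regions give
  undefined regularity; a fully perfused image is an error for
  `find_faz()`.
* Undefined metric values propagate as `NA` through normalization and
  scoring; a metric with fewer than two finite baselines is unusable and
  reported censored.

## Problem sizes used by the test-suite

The packaged checks run two geometries. Pipeline-fidelity checks
(segmentation recall, FAZ recovery) use the full canonical geometry
(304 → 1824 px). Sweep-heavy checks (tier ordering: 20 specimens × 50
levels × 100 iterations = 100,000 rebuilt images) use the same physical
field rasterized at 456 px with the capillary caliber and area thresholds
scaled accordingly (3-px caliber, 51·(456/1824)² px² PICA floor), and
operate on the ground-truth segmentation so they probe the simulator and
scoring stages in isolation. Physical quantities (FAZ area, vessel
density, PICA areas in mm²) are scale-invariant by construction; per-pixel
metrics such as VPI are scale-dependent and are only ever compared within
one geometry.

## Known limitations

* Sensitivities estimated from 100 iterations carry visibly more sampling
  noise than the canonical 1000; ordering statements are stable, individual
  crossings move by a fraction of a grid step.
* The automated FAZ-cleanup rule deletes only isolated blobs; a noise
  filament touching the rim survives, exactly as it would under the
  interactive procedure it replaces only if the operator kept it.
* The FAZ detector inherits the top-10 scan of the published procedure; on
  heavily fragmented images at extreme loss the center component can drop
  out of the top 10, in which case the fallback (nearest component, with a
  warning) applies.
* `vci_norm_constant()` depends on the exact disk rasterization convention;
  alternatives (geometric center, inscribed radius 911.5) move the constant
  by under 0.2%.
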