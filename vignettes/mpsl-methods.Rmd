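---
title: "Morphological processing and successive localization for 4D target segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological processing and successive localization for 4D target segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsl)
```

## The problem

Respiratory-gated CT (4DCT) reconstructs roughly ten 3D volumes per
breathing cycle, one per 10% phase bin. Radiotherapy planning for lung
tumors needs the gross target volume (GTV) delineated on *every* phase to
quantify how the target moves and deforms during free breathing. Manual
contouring of ten volumes is slow and observer-dependent, and deformable
registration — the usual automation — still requires a manual contour on
one reference phase before it can propagate anything. This package
implements a contour-free alternative: morphological processing and
successive localization (MPSL), which segments the GTV on each phase
directly from intensity and size priors, then tracks the segmented
target's center of geometry (COG) across phases.

## The pipeline

For a voxel set $A$ and a structuring element $B$ (a finite set of integer
offsets $b$ containing the origin), the package uses the set-theoretic
morphological operations

$$A \oplus B = \{\, c \mid c = a + b \ \text{for some}\ a \in A,\ b \in B \,\},
\qquad
A \ominus B = \{\, x \mid x + b \in A \ \text{for every}\ b \in B \,\}.$$

`segment_phase()` runs, in order:

1. **Dual-range mask.** A voxel is kept when its HU falls inside either of
   two closed intensity intervals — one bracketing the tumor, one the
   surrounding tissue. Tumor and soft tissue generally overlap in
   intensity, which is exactly why a plain threshold cannot isolate the
   target; the mask deliberately includes both.
2. **Erosion** with a configurable element. This severs thin connections
   between the tumor and same-intensity structures (chest wall,
   diaphragm), producing disjoint regions.
3. **Union-find labeling.** Connected components of the eroded mask are
   labeled with a disjoint-set structure with path compression (in C++);
   labels are assigned in ascending order of each region's first voxel in
   x-fastest scan order, so labeling is fully deterministic.
4. **Volume window.** Regions whose volume falls outside
   `[volume_min_cc, volume_max_cc]` are discarded. Note the window applies
   to *eroded* volumes: a 113 cc sphere eroded by a 5 mm ball retains
   roughly 65 cc, so the window must be set generously around the eroded
   size, not the anatomical size.
5. **Selection.** One surviving region is chosen: the largest by default
   (with a warning listing all survivors), the one containing the seed
   click in seeded mode, or the localized candidate in 4D mode (below).
6. **Dilation** of the selected region with the *same* element used for
   erosion, restoring the target to its approximate original extent.
7. **Masking.** The dilated region is intersected with the stage-1 mask.
   How to keep the restoring dilation from annexing background is a
   genuinely open design point; intersecting with the original threshold
   mask is the morphological-reconstruction-flavored choice and guarantees
   the result never leaves thresholded tissue. The final mask is then
   reduced to the single connected component containing the selected
   region.

### Successive localization

Across a 4D series, `segment_series()` segments phase 0 unconstrained (or
from a seed click) and then restricts each later phase's candidate
selection to regions whose centroid lies inside the previous phase's GTV
bounding box expanded by `localization_margin_mm` on every axis; among
those, the candidate nearest the previous COG wins. If no candidate lies
in the expanded box the phase falls back to the unrestricted rule and is
flagged `localization_fallback`. The expansion-margin mechanism is this
package's concrete reading of "successive localization" — the temporal
prior that a breathing target cannot jump arbitrarily far between
adjacent phases; the default margin of 15 mm comfortably covers typical
respiratory excursions.

### Seeded mode

With `seed_point` set, the tumor intensity range is replaced by the
min/max HU over the cubic neighborhood of half-width
`seed_neighborhood_halfwidth` voxels around the click, and the region
containing the seed is selected. The click must be *inside* the tumor:
a click near the boundary legitimately samples surrounding lung in its
neighborhood, widening the derived range until the mask merges with the
background (the pipeline then reports no target in the volume window
rather than guessing). When the seed lies in the interior of what the
unseeded pipeline would have found, seeded and unseeded runs return the
identical mask — a property the test suite checks.

## Parameters

| Parameter | Units | Default | Role |
|---|---|---|---|
| `tumor_range` | HU | [-150, 150] | closed interval bracketing tumor intensities (water-equivalent tissue ± margin) |
| `surround_range` | HU | [-120, 250] | closed interval for surrounding soft tissue |
| `volume_min_cc`, `volume_max_cc` | cc | 1, 300 | window on **eroded** region volumes |
| `radius_mm` | mm | 5 | erosion/dilation radius; must exceed the half-thickness of any attachment neck to sever it |
| `element_shape` | — | ball | ellipsoidal ball (respects anisotropic spacing) or box |
| `mode` | — | 3d | volumetric, or per-slice 2D |
| `connectivity` | — | face | 6-neighborhood; face-only maximizes the disconnecting power of erosion |
| `localization_margin_mm` | mm | 15 | bounding-box expansion between phases; also the seed fallback radius |
| `seed_neighborhood_halfwidth` | voxels | 2 | half-width of the click neighborhood |

The intensity ranges, volume window and radius are *protocol choices*: the
method's published form leaves them to be chosen empirically per
population, and the defaults here are this package's pragmatic settings
for water-equivalent lung tumors, not reference values.

### Numerical choices

* **mm-to-voxel rounding.** Per-axis element radii are
  `round(radius_mm / spacing)` with half-way cases rounded *up*
  (deterministic, documented); a radius that rounds to zero on every axis
  degenerates to `{origin}` with a warning.
* **Boundary handling.** Out-of-bounds is background: erosion treats the
  outside as empty and dilation discards results beyond the array. The
  conservative choice — nothing is ever fabricated outside the scanned
  field of view.
* **Threshold conventions.** Intensity ranges are closed intervals; the
  single-threshold baseline (`threshold_baseline()`, default -83 HU)
  keeps voxels *strictly above* the cutoff.
* **Tie-breaks.** Multiple volume-window survivors resolve to the largest
  region (with a warning); equal-volume ties resolve to the smaller
  label, which is itself deterministic by the scan-order labeling rule.
* **2D mode.** The whole pipeline runs per slice and the results are
  stacked; each slice keeps its largest surviving region. The volume
  window is then interpreted directly as a per-slice slab volume
  (in-plane area × slice thickness), so 2D windows are numerically much
  smaller than 3D ones. Slice-wise processing has no cross-slice
  localization, so it relies on a tumor-specific intensity range far more
  than the 3D mode does.
* **Empty-mask metric conventions.** `overlap_metrics()` returns
  dice = sensitivity = PPV = 1 when truth and test are both empty
  (perfect agreement on absence) and all 0 when exactly one is empty.
  `metrics_table()` reports the sample (n-1) standard deviation, 0 with a
  flag for a single case.
* **Trajectory errors.** Relative COG error is measured on the
  displacement-from-phase-0 vector (the motion profile), not on absolute
  position, with guard $\varepsilon$ = one voxel diagonal: phases whose
  true displacement is below $\varepsilon$ report absolute error in mm
  and are flagged instead of dividing by a near-zero denominator.

## The synthetic phantom

`phantom_spec()` / `generate_phantom()` emulate a chest-phantom
validation experiment: an elliptic-cylinder body shell of soft tissue
(+40 HU) with an inner wall ring, an ellipsoidal lung cavity (-800 HU),
and a water-HU sphere (default 6 cm diameter — the classic phantom
insert) displaced per phase by a known waveform, plus independent
Gaussian noise (default SD 20 HU) seeded per `(rng_seed, phase)` so
phases are independent yet bit-reproducible. Sinusoidal motion uses
displacement $a\cos(2\pi k/10)$ for phase $k$, so the sampled phases hit
both extremes and the COG span is exactly twice the amplitude. Voxels
belong to a shape iff their center lies inside the analytic surface; the
truth trajectory records the *analytic* sphere centers and the voxelized
volumes. Optional geometries reproduce the two classic failure modes of
threshold/region-growing segmentation: a tissue neck attaching the
sphere to the chest wall, and a diaphragm-like dome of tumor-equivalent
HU on the cavity floor (`phantom_suite()` bundles both, plus a small
low-contrast sphere).

The default grid is 64 × 64 × 56 voxels at 2 × 2 × 2.5 mm — a
deliberately modest problem size (~130 cc sphere in a 128 × 128 × 140 mm
field) that keeps a full 10-phase, 5-seed validation run under half a
minute while preserving the 2.5 mm slice thickness typical of 4DCT
protocols.

What the phantom does *not* emulate: X-ray physics (beam hardening,
reconstruction artifacts, partial-volume blur at tissue interfaces),
irregular patient breathing beyond the custom displacement list, tumor
deformation (motion is rigid), and textured parenchyma (tissues are
uniform plus white noise). Passing the phantom suite therefore
demonstrates the pipeline's geometric and numerical correctness — exact
morphology, labeling, volume bookkeeping, sub-voxel COG tracking — but
not robustness to clinical image texture; on patient data the intensity
ranges and volume window carry far more burden than they do here.

## Known limitations

* Tissue necks thicker than `radius_mm` are not severed; the remedy
  (larger radius) trades off against destroying small targets, which is
  inherent to morphological separation.
* The volume window is a single static prior; a target whose eroded
  volume drifts outside the window (e.g. severe deformation) triggers a
  no-target failure rather than a degraded result, by design.
* 2D mode offers no cross-slice consistency; it is faithful to the
  method's slice-wise variant but the 3D mode should be preferred
  whenever volumetric data are available.
* DICOM support covers uncompressed little-endian single-frame CT
  slices, the common export format; compressed transfer syntaxes are
  rejected with a clear error rather than misread.
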