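---
title: "Quantifying ice in frozen porous foods from 3D tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ice in frozen porous foods from 3D tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a porous food such as sponge cake is frozen, the water it contains
crystallizes in two distinct places: as small crystals embedded in the
starch matrix, and as a layer of ice deposited on the walls of the air
pores. Where the ice ends up depends strongly on the freezing rate:
rapid freezing nucleates many small crystals inside the matrix before
water can move, while slow freezing leaves time for evapo-condensation
— water vapour migrating from the warm matrix into the pores and
condensing as a thick conformal ice layer on the pore walls. The spatial
distribution of ice controls thawed texture and drying behaviour, so
quantifying it is of direct technological interest.

Synchrotron micro-CT resolves the three constituents — air, ice and
starch — as three well-separated grey-level populations in a 3D volume.
`icemorph` implements the complete analysis chain from such a grey-level
volume to quantitative morphometric descriptors, together with a
synthetic phantom generator that provides ground-truth-labelled test
volumes emulating both freezing regimes.

## The analysis chain

1. **Three-phase segmentation** (`segment()`). Two grey thresholds
   separate air (darkest), ice (intermediate) and starch (brightest).
   The default thresholds minimize the three-class within-class
   variance on a 256-bin histogram (three-class Otsu, found by
   exhaustive search); manual thresholds are first-class, and a volume
   whose histogram does not show three detectable modes (an unfrozen
   air/starch sample, or a constant image) raises an error rather than
   returning meaningless cuts. Mode detection uses local maxima of the
   lightly smoothed histogram with a prominence of at least 5% of the
   tallest peak. Threshold boundaries are half-open and
   lower-inclusive on the brighter class; this convention is arbitrary
   but fixed, so segmentations are bit-reproducible.
2. **Matrix closing** (`close_matrix()`). The starch mask is closed
   with a digitized Euclidean ball (default radius 16 voxels),
   producing the *matrix*: the starch phase with embedded ice crystals
   and narrow gaps filled. The volume is padded with background before
   dilation and cropped after erosion, so no artificial matrix is
   created at the volume faces. The ball radius must exceed the
   half-width of the embedded crystals to be filled and stay below the
   pore width; 16 voxels is the appropriate default at tomographic
   resolution and works across the phantom presets shipped here.
3. **Ice localization** (`partition_ice()`). Ice is split by logical
   operations into ice *inside* the matrix (ice AND matrix) and ice
   *outside* (ice AND NOT matrix). The intersection is taken with the
   closed matrix, not the raw starch mask — raw starch and ice are
   disjoint by construction, so intersecting with raw starch would
   always yield an empty inside phase.
4. **Morphometry.**
   - *Volume fractions* (`volume_fractions()`) are exact voxel counts:
     porosity (air over total), the ice fraction of the solid (ice over
     ice + starch), and the outside share of the ice. A volume with no
     ice reports the outside share as `NA` — the 0/0 must stay visible,
     never coerced to zero.
   - *Vertical profiles* (`vertical_profile()`) evaluate any of those
     fractions per z-slab.
   - *Specific surface area* (`specific_surface_area()`) divides the
     interface area between two phases by the analysed volume
     (mm^-1). The analysed (cropped) volume is the reference volume.
     The default estimator is the Crofton formula with 13 discrete
     directions, weighted by the spherical-Voronoi areas of the
     direction set; it is accurate to well under 5% for isotropically
     oriented interfaces (a digitized sphere), but any fixed-direction
     Crofton estimator is biased for perfectly planar, axis-aligned
     interfaces — about −7% in the worst orientation. A `"gradient"`
     method (coarea integral of the Gaussian-smoothed indicator,
     exact for planes) is provided as a cross-check for the special
     case where the two phases partition the volume.
   - *Local thickness* (`local_thickness()`) implements the
     largest-inscribed-sphere definition: exact separable squared
     Euclidean distance transform, distance-ridge extraction
     (a centre is pruned only when its sphere is provably contained in
     a neighbour's, so coverage is never lost), and sphere
     superposition. Ties on equal diameters resolve to the maximum,
     which makes the result order-independent. The image border is not
     treated as background, so a slab spanning the volume measures its
     true thickness; an entirely foreground volume has infinite
     thickness. `thickness_distribution()` accumulates the
     volume-weighted cumulative curve ending at 100%.
   - *Mean curvature* (`mean_curvature_field()`). The binary indicator
     is smoothed with a Gaussian (default sigma 2 voxels) and the
     principal curvatures of its level sets are evaluated from the
     gradient and Hessian of the smoothed field; the mean curvature is
     their average. Samples are taken in the band around the 0.5
     iso-surface (gradient magnitude at least 5% of its maximum) and
     weighted by the coarea density (gradient magnitude times voxel
     face area), which converges to the interface area measure.
     Averaging across the band cancels the first-order dependence of
     level-set curvature on the level, so a digitized 1 mm pore
     measures within about 1% of its analytic −2 mm^-1. Convex
     protrusions of the mask are positive, concave walls negative.
     Sigma trades noise robustness against resolution: below 1 voxel
     the derivatives are unstable (a warning is raised); much above 3
     voxels, features smaller than sigma are smoothed away.
     `curvature_distribution()` reports the area-weighted occurrence
     ratio per curvature bin (default width 0.5 mm^-1), summing to
     100%.
5. **REV analysis** (`rev_curve()`,
   `smallest_representative_size()`). Phase fractions are computed on
   centred sub-cubes of increasing size and compared with the mean ±
   sd across the full replicate volumes. "Representative" is
   operationalized as lying inside that ± sd band (the shaded band of
   a convergence plot) for the size in question and all larger sizes;
   a random-placement mode averages several placements per size for a
   stricter reading. Centred placement is the default because a
   convergence plot shows one point per size.
6. **Condition reports** (`run_pipeline()`). Per-volume results are
   aggregated per condition as arithmetic mean ± sd over the
   per-volume fractions — not as ratios of pooled voxel counts — and
   written as CSV tables plus a JSON summary. Significance testing
   (ANOVA / multiple comparisons) is deliberately out of scope; the
   per-volume tables give users everything needed to run their own
   tests. `derived_ratio()` produces headline integer percentages such
   as the share of total ice formed inside the matrix.

## The phantom generator

No public micro-CT volumes of frozen sponge cake exist, so the package
ships a synthetic generator (`generate_phantom()`) whose ground truth
is exact by construction:

- **Pore space**: a Gaussian random field (white noise smoothed at
  sigma = `pore_scale` / 2), thresholded at the porosity quantile.
  This gives a stationary, connected, multi-scale pore network and
  hits the target porosity essentially exactly. Default porosity 0.6
  matches a typical sponge cake; `pore_scale` (default 80 µm) is a
  free parameter — real cakes show pores from tens of micrometres to a
  millimetre, and the default is chosen so that several pores fit in a
  desk-scale volume while remaining wide relative to the wall-ice
  layer and the closing ball.
- **Wall ice**: every air voxel within the requested thickness of the
  solid surface, i.e. a Euclidean dilation of the solid into the air
  relabelled as ice. This is exactly a conformal shell; a warning is
  emitted when the shell reaches the deepest pore radius and pores
  close entirely.
- **Internal crystals**: axis-aligned cuboids with edges drawn
  uniformly from a size range, centred on solid voxels and clipped to
  the solid. Cuboids match the prismatic crystal habit seen in frozen
  starch matrices and keep analytic volume checks possible.
- **Rendering**: per-phase grey means (both ice phases share one
  mean), additive Gaussian noise, then Gaussian blur. Defaults (means
  50/120/200, noise sigma 10, blur 1.4 µm) give three cleanly
  separable histogram modes with realistic partial-volume mixing at
  interfaces.

One seed is set per phantom and sub-steps draw in a fixed order, so a
spec reproduces bit-identically.

The presets encode the two freezing regimes: `"fast"` has a thin 2 µm
wall layer and 400 small crystals (8–20 µm), `"slow"` a 24 µm wall
layer and 40 larger crystals (20–45 µm), at 2 µm voxels in a 112³
volume. These sizes mirror the characteristic ice thicknesses reported
for the two regimes (95% of fast inside-ice below ~20 µm, slow
~20–45 µm; wall ice 20–30 µm under slow freezing) and reproduce the
qualitative signatures: most ice inside the matrix under fast freezing
and at the pore walls under slow freezing, a larger ice–starch
interface area under fast freezing, and right-shifted thickness
distributions under slow freezing.

What the phantom does **not** emulate: physically based crystal growth
(crystal shapes and spatial correlation with the thermal gradient),
beam hardening, reconstruction artefacts (rings, phase-contrast
fringes), anisotropic pore shapes, and the nanoporosity that real
cakes show below tomographic resolution. Passing the recovery tests
therefore demonstrates the correctness of the measurement chain on
geometry of known truth — not the segmentability of every real scan.

Because the wall-ice layer keeps its physical thickness (24 µm) while
the pores are scaled down relative to a real cake, the slow preset
converts a larger share of the air into wall ice than a real slow-frozen
sample would; the regime orderings are unaffected.

## Numerical choices

- Distance transform: exact separable squared EDT; all comparisons on
  squared integers, so no floating-point ties.
- Closing ball: digitized Euclidean ball (voxel included iff its
  centre is within the radius), consistent between dilation and
  erosion.
- Crofton direction weights: 0.04577789120476 (3 axes),
  0.03698062787608 (6 face diagonals), 0.03519563978232 (4 body
  diagonals); they sum to 1/2 over the 13 unsigned directions.
- Curvature principal values: from mean curvature H and Gaussian
  curvature K of the implicit surface as H ± sqrt(max(H² − K, 0)).
- Thresholding: histogram bin edges span the observed grey range;
  the returned thresholds are bin-edge values.
- Degenerate inputs: constant volumes, masks without an interface,
  empty thickness maps, zero-ice volumes and unattainable phantom
  parameterizations raise classed errors (or `NA` where a quantity is
  genuinely undefined) instead of silently returning zeros.

## Problem sizes

The shipped tests and examples run phantoms at 48³–112³ voxels and
analytic shapes at up to 100³; a full phantom pipeline at these sizes
takes seconds to a couple of minutes on one CPU. All operations scale
to full tomographic volumes (2048³) in the same code path, limited
only by memory.

## Worked example

```{r, eval = FALSE}
library(icemorph)

ph <- generate_phantom(phantom_preset("fast", seed = 1))
seg <- segment(ph$grey, closing_radius = 16)
volume_fractions(seg$labels)

ice_in <- seg$labels$data == phase_codes()[["ice_inside"]]
td <- thickness_distribution(local_thickness(ice_in, ph$grey$voxel_size))
autoplot(td)

report <- run_pipeline(list(
  fast = lapply(1:2, function(s) generate_phantom(phantom_preset("fast", seed = s))),
  slow = lapply(1:2, function(s) generate_phantom(phantom_preset("slow", seed = s)))))
derived_ratio(report, "ice_inside", "ice", "fast")
```

## Thermophysical helpers

Independent of the imaging chain, the package includes the closed-form
calculations used alongside tomography: oven-drying water content,
freezable water from DSC melting enthalpy relative to the latent heat
of ice (334 J/g) — the water content enters as a mass *fraction*; the
percent annotation sometimes attached to that symbol is dimensionally
inconsistent with the printed results — harmonic mass-fraction mixture
density, and porosity from the apparent/theoretical density ratio
(as 1 − ratio; the ratio itself is not a porosity). Conversion of
freezable water to an ice volume fraction is not implemented: it
requires density assumptions for the unfrozen matrix that are not
determined by the available inputs.

## Known limitations

- The Crofton estimator's plane bias (above) matters only for
  perfectly flat, axis-aligned interfaces; natural interfaces are
  orientation-averaged.
- Local thickness is defined on voxel centres; objects one voxel wide
  measure two voxels thick (the inscribed sphere reaches the
  neighbouring background centre). This matches the standard
  distance-transform implementations of the definition.
- The curvature estimator requires features larger than the smoothing
  sigma; sub-sigma roughness is reported as flat.
- Multi-scan stitching, reconstruction, and ML-based segmentation are
  out of scope.
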