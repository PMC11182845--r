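---
title: "Quantifying tau relative to individual blood vessels in 3D"
author: "perivasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tau relative to individual blood vessels in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perivasc)
```

## The measurement problem

In cleared human cortex imaged in 3D, phosphorylated tau (AT8) accumulates
along the abluminal surface of some arterioles, in a diffuse pattern distinct
from neurofibrillary tangles (NFTs). Quantifying this requires expressing
every tau-positive voxel, and every segmented neuron or tangle, in
*vessel-relative* coordinates: its Euclidean distance from the vessel surface
(`d_surface`, µm) and its arc-length position along the vessel centerline
(`s_along`, µm). On top of those coordinates the pipeline builds:

* 10 µm along-vessel **segment bins**, each scored by its *surface tau* —
  the mean normalized tau intensity within 3 µm of the vessel mask;
* a cohort-wide **decile ranking** of segments by surface tau
  (decile 10 = highest);
* **radial profiles**: percent change of tau intensity versus distance from
  the surface, relative to the whole-image mean, per decile and donor;
* **shell densities**: neurons and NFTs counted within 30 µm of the surface
  and divided by the voxel-counted volume of each bin's shell (per mm³);
* a one-way **repeated-measures ANOVA** of the NFT-bearing neuron fraction
  across deciles, with the donor as the repeated factor.

All distances are in µm, volumes in mm³ (µm³ × 10⁻⁹), and anisotropic voxel
spacing is carried through every computation. Voxel `(i, j, k)` (1-based) has
world position `((i−1)·sx, (j−1)·sy, (k−1)·sz)`; one fixed convention removes
any half-voxel ambiguity.

## Geometry

**Distance field.** `compute_distance_field()` is an exact separable
Euclidean distance transform (lower-envelope-of-parabolas, one pass per
axis, axis-specific sampling intervals). The value at a voxel is the
distance to the nearest *mask voxel center*, and 0 inside the mask: tau is
measured away from the surface, never with negative "inside" distances, so
the 3 µm surface window covers the first 3 µm of abluminal tissue plus the
mask itself.

**Centerline.** Vessels are traced as single unbranched tubes, so the
centerline is extracted from the mask geometry directly rather than by
topological thinning:

1. *End regions* by a farthest-pair double sweep of geodesic (within-mask)
   distance over the 26-neighborhood graph with Euclidean edge weights.
2. *Interior path* as centroids of geodesic-distance level sets — away from
   the end caps these level sets are nearly planar cross-sections, so their
   centroids lie on the medial axis; level sets within two tube radii of a
   cap are discarded (a point source makes them spherical there).
3. *Medial endpoints* as the voxel maximizing `g + 1.5·depth`, where `g` is
   geodesic distance from the far end and `depth` the distance to the
   background: along the axis this score rises at unit rate until the medial
   axis meets the end cap and falls beyond it. The voxelized endpoint is then
   refined to sub-voxel position using the identity that, on the medial axis,
   the distance to the mask exit along the axis equals the local depth — the
   voxelization inflations of the two terms cancel.
4. Resampling at ≤ 1 µm steps, an end-preserving 5-point moving average, and
   cumulative arc length. `s = 0` is placed at the endpoint with the
   lexicographically smaller world coordinates, making "the start of the
   centerline" deterministic.

On analytic phantoms (capsule-ended cylinders, quarter arcs, helices;
isotropic and 1:2 anisotropic grids; axis-aligned, diagonal, and oblique
orientations) arc lengths are recovered within ±2 % and centerline points
stay within one voxel of the true axis; the test suite asserts 5 %, the
tolerance appropriate for radius-3-voxel tubes.

**Along-vessel coordinate.** `assign_along_distance()` gives each point the
arc length of its nearest centerline vertex, ties toward the smaller `s`.
With ≤ 1 µm vertex spacing the quantization is below the voxel size.

**Diameter.** At 25/50/75 % of arc length (deterministic sites, not random,
so the measure is reproducible), the maximal chord through the centerline
point perpendicular to the local tangent is found over 36 sampled in-plane
directions; the mean of the three chords is the vessel diameter, mirroring
diameter measurement by averaging three line measures at separate locations.

## Intensity normalization

Staining intensity varies across samples, so raw tau is mapped through a
three-anchor piecewise-linear function. Anchors are the per-category grand
means of operator-sampled sites — background, autofluorescence, and
tau-positive, by convention 10 measurements at each of 3 depths — and they
must be strictly increasing. The canonical targets are fixed at (0, 1, 2):
no target scale is inherent to the data, and a unit-spaced scale makes
"one autofluorescence-to-positive interval" the natural unit. Between
anchors the map is linear; beyond the end anchors it extrapolates linearly
with the adjacent segment's slope rather than clamping, so extreme tangle
intensities keep their ordering. Grand means (not per-depth maps) define the
map; a per-depth variant would be a straightforward extension.

Two affinely related acquisitions of the same tissue, with correspondingly
shifted anchors, normalize to identical volumes (the property the
cross-sample comparisons rely on); the suite asserts agreement within 1e-6.

Secondary rescalings — to control-donor means, or to the whole-image mean
for radial profiles, where 0 % change means "no different from the average
tau of the image" — are plain divisions handled by
`normalize_to_reference()`.

## Bins, deciles, profiles, densities

Bins `[0,10), [10,20), …` tile `[0, vessel length]`; a trailing bin shorter
than 10 µm is kept and flagged. Bins without surface voxels are excluded
from ranking. Ranking pools all vessels and donors of a group by default,
because cross-donor figures compare segments on one common scale; ties break
by `(vessel_id, bin_index)` so reruns are identical. A voxel within reach of
two vessels is attributed to the nearer one only (ties to the lower vessel
id), preventing double counting; the same rule applies to object assignment
and shell volumes.

Shell volumes are voxel counts (within 30 µm, outside the lumen, attributed
to the bin by `s_along`) times the voxel volume. On a radius-8 µm cylinder
with a 30 µm shell the interior bins agree with the analytic annulus
π((r+30)² − r²)·10 µm³ within ~1.4 % at 1 µm spacing.

A neuron is counted NFT-bearing when an NFT centroid lies within 5 µm of its
centroid. The matching rule between channels is not standardized in this
field; 5 µm is roughly half a soma diameter, and the radius is configurable
and recorded in every manifest.

## The statistical layer

`rm_anova()` is a one-way within-subject decomposition: donors are subjects,
deciles the repeated factor; `SS_subject` is absorbed,
`F = (SS_effect/df_effect)/(SS_error/df_error)` with the subject × decile
interaction as error. The reported `R2` is partial eta squared,
`SS_effect/(SS_effect + SS_error)` — stated explicitly because R² reporting
conventions vary. Decile levels missing in any donor are dropped
(complete-case on levels) and listed in the result; imputation is
deliberately avoided. No sphericity correction is applied by default. The
implementation is explicit sums of squares; `aov(value ~ decile +
Error(donor))` serves as an independent cross-check in the tests.

`two_group_test()` gates on Shapiro–Wilk at α = 0.05 in each group: both
normal → equal-variance two-tailed t test, otherwise two-sided Mann–Whitney
U. A constant group cannot be declared normal and routes to the rank test,
except two equal constant groups, which report the degenerate branch with
p = 1. `lane_normalize_and_test()` divides lane totals by the control-lane
mean (controls average 1 by construction) and applies a one-tailed
equal-variance t test in the stated direction.

## The synthetic scene generator

No donor imaging ships with the package, so every stage is exercised on
seeded volumetric phantoms with the statistical structure the analysis
assumes:

* **Vessels**: straight, arc, or helix paths with arc-length
  parameterization (closed-form lengths), rasterized as the set of voxel
  centers within the tube radius of the continuous path. Defaults emulate
  non-capillary arterioles of ~16–20 µm diameter spanning cortical layers.
* **Intensity**: Gaussian background noise (mean 10, SD 3), low-frequency
  autofluorescence blotches (rectified trilinearly-upsampled coarse noise
  reaching the autofluorescence level of 40), and per-segment surface
  enrichment `amplitude·exp(−d_surface/decay)` on chosen arc intervals,
  clipped at 0. The three regime levels (10, 40, 100) provide ground-truth
  anchors. Gaussian noise is the minimal testable choice; no optical PSF or
  light-sheet striping is simulated.
* **Objects**: neuron count ~ Poisson(rate × tissue volume), uniform outside
  lumina, at a default 30 000 neurons/mm³ (the order of magnitude of human
  temporal cortex). Each neuron is NFT-positive with probability
  `clamp(base_prob + slope × score, 0, 1)` where `score` is the true
  normalized surface tau of its nearest vessel segment (0 beyond 30 µm).
  The link is linear-with-clamping rather than logistic so recovery tests
  have closed-form expectations. NFT-positive neurons contribute a
  colocated `nft` object.
* **Layers**: labels 1–6 assigned by z-planes, so a spanning vessel crosses
  all layers.

Identical spec + seed reproduces a bit-identical bundle on disk.

The true tau decay length of vascular tau is not an established quantity;
the generator's defaults (10–20 µm) are scene design choices, not estimates
of tissue biology.

## Evaluation scenarios and problem sizes

`example_scene_spec()` fixes two scenarios used throughout the tests and by
`scripts/acceptance.R`:

* `"enrichment"`: one straight radius-8 µm vessel fully inside an isotropic
  44×44×132 µm volume, two enriched arcs (41–49 and 81–89 µm, amplitude 90 =
  30× the background noise SD, decay 20 µm), no objects. Each arc sits 1 µm
  inside a single 10 µm bin so that, given sub-voxel centerline end accuracy,
  neighboring bins stay enrichment-free and the ranking can be scored
  against ground truth. Two arcs per vessel (rather than one) keep the
  enriched fraction at 2 of ~12 bins — comfortably inside the top two
  deciles of a 20-scene cohort — while contributing enough signal to the
  whole-image mean that purely noise-selected high bins profile at or below
  0 % change, the qualitative pattern seen in tissue.
* `"density"`: the same vessel with no enrichment, 50 000 neurons/mm³ and a
  decile-independent NFT probability, for the no-geometric-confound null
  (density–decile slope within 2 SE of 0) and Poisson-rate recovery.

Cohorts of 20 such scenes run in about a minute each; ANOVA calibration uses
500 table-level null cohorts (6 donors × 10 deciles × 40 neurons/cell) and
power uses 200 cohorts with NFT probability rising from 0.05 to 0.25 across
deciles — a strong but plausible effect under which detection should be
near-certain. These sizes keep the full suite and the acceptance script
within a few minutes on one CPU while leaving every recovery margin wide.

Passing these scenarios shows the *machinery* is correct — coordinates,
binning, ranking, normalization, densities, and test statistics — under the
generator's assumptions. It does not validate performance on real cleared
tissue, where vessel masks are imperfect, intensity regimes drift within a
volume, autofluorescence is structured, and segmentation errors correlate
with depth.

## File formats and the command line

Volumes are multi-page TIFF (unsigned 8/16-bit integer, spacing in a JSON
sidecar — as acquired microscope images are) or HDF5 (any numeric data, used
for normalized volumes and distance fields); both round-trip exactly. Object
tables, segment bins, and profiles are CSV; configuration and manifests are
JSON. Spacing is a required input everywhere: confocal stacks are
anisotropic and guessing a z-step silently corrupts every distance.

`run_cli()` (and the thin `inst/cli/perivasc` Rscript) drives the stages
`simulate`, `geometry`, `normalize`, `profile`, `density`, `stats`, and
`report` over a bundle directory; every stage writes a manifest with its
configuration, seed, and input hashes. `stats` treats bundles as donors when
several are given (`--inputs`), and falls back to vessels as subjects for a
single bundle — adequate for smoke runs, under-powered by design at that
scale.

## Known limitations

* Centerlines assume unbranched tubes; bifurcating masks are rejected rather
  than traced.
* Vessels clipped flat by the volume border lose ~2 µm of centerline at each
  clipped end, shifting the s-origin by the same amount; segment boundaries
  inherit that offset.
* The decile scope pools all vessels of a run; per-donor ranking is
  supported but the cohort-wide default is what cross-donor comparisons
  assume.
* The NFT–neuron colocalization radius is an explicit stand-in for an
  unstated matching rule; conclusions sensitive to it should be checked
  across radii.
* `rm_anova` applies no sphericity correction by default, matching the
  minimal named procedure; with 10 deciles and few donors the F test is
  approximate.
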