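# perivasc

Vessel-relative quantification of perivascular tau pathology in 3D
microscopy volumes.

In Alzheimer's disease, phosphorylated tau (AT8) can accumulate along the
surface of cortical arterioles, distinct from neurofibrillary tangles
(NFTs), and the local tangle burden rises where that vascular surface tau is
high. Measuring this requires expressing every voxel and every segmented
cell in coordinates relative to an individually segmented blood vessel.
`perivasc` implements that measurement pipeline for researchers analyzing
cleared-tissue confocal or light-sheet volumes:

* **Vessel geometry** — anisotropy-aware exact Euclidean distance fields
  (`d`, µm from the vessel surface, 0 inside the mask) and arc-length
  parameterized centerlines (`s`, µm along the vessel) from binary tube
  masks, plus diameters from perpendicular chords at quartile sites.
* **Cross-sample intensity normalization** — the three-anchor piecewise
  linear map: per-sample means of background, autofluorescence, and
  tau-positive reference sites (10 sites × 3 depths each) are sent to the
  canonical scale (0, 1, 2), linear within segments and linearly
  extrapolated beyond.
* **Segment scoring** — 10 µm along-vessel bins scored by *surface tau*
  (mean normalized intensity within 3 µm of the mask), ranked into deciles
  across the pooled cohort; per-vessel heatmaps of
  `log10(surface tau / whole-image mean)`.
* **Radial profiles** — percent change of tau versus distance from the
  surface (1 µm steps, out to 100 µm), relative to each donor's whole-image
  mean, per decile, with across-donor mean ± SEM.
* **Object densities** — neurons and NFTs within a 30 µm shell, assigned to
  the nearest vessel, counted per bin and divided by the voxel-counted
  shell volume (mm³); the percent of neurons bearing an NFT (colocalization
  radius 5 µm) per donor × decile.
* **Statistics** — one-way repeated-measures ANOVA of NFT fraction across
  deciles (donor as subject; `R²` reported as partial eta squared
  `SS_effect/(SS_effect+SS_error)`), Shapiro–Wilk-gated two-group tests
  (t vs Mann–Whitney U), and control-normalized lane intensities with
  one-tailed t tests.
* **Synthetic scenes** — a seeded generator of volumetric phantoms (tubular
  vessels, three intensity regimes, surface-anchored exponentially decaying
  tau enrichment, Poisson-placed neurons whose NFT probability rises with
  local surface tau) so the whole pipeline is testable without donor data.

## Worked example

```r
library(perivasc)

# a synthetic scene: one radius-8 um vessel with two tau-enriched arcs
spec <- example_scene_spec("enrichment", seed = 42)
ps <- process_scene(spec, id_prefix = "demo")
ps$vessels[[1]]
#> <vessel_model> 'demo_v01': length 116.2 um, diameter 17.2 um, 26080 mask voxels

# 10 um segments ranked by surface tau: the two enriched arcs (41-49 and
# 81-89 um) surface in the top decile
bins <- assign_deciles(ps$bins)
subset(bins, decile >= 9, select = c(bin_index, s_start, s_end, surface_mean, decile))
#>    bin_index s_start s_end surface_mean decile
#> 5          5      40    50     1.712708     10
#> 9          9      80    90     1.662385     10
#> 11        11     100   110     0.361772      9

# radial profile of the top decile: strong enrichment at the vessel surface,
# decaying with distance (percent change vs the whole-image mean)
prof <- radial_profile(ps$records, bins, c(demo = ps$image_mean),
                       setNames("demo", ps$vessels[[1]]$vessel_id))
head(subset(prof$summary, decile == 10), 4)
#>    decile distance_um     mean sem n
#> 10     10           0 353.9686   0 1
#> 20     10           1 340.9515   0 1
#> 30     10           2 324.5329   0 1
#> 40     10           3 312.5131   0 1

# association between surface-tau decile and NFT-bearing neuron fraction:
# 6 donors x 10 deciles, NFT probability rising 0.05 -> 0.25 across deciles
set.seed(1)
cohort <- simulate_nft_cohort(n_donors = 6, n_deciles = 10,
                              neurons_per_cell = 40, base_prob = 0.05,
                              slope = 0.2)
rm_anova(cohort)
#> Repeated-measures ANOVA: F(9, 45) = 10.949, p = 8.596e-09, R2 = 0.686 (6 subjects)
```

The surface means are on the canonical normalized scale (0 = background,
1 = autofluorescence, 2 = tau-positive); the measured diameter (17.2 µm)
recovers the 16 µm construction within the voxel resolution; the profile
shows the designed exponential surface enrichment; and the ANOVA detects
the designed decile trend with most of the decile-by-donor variance
explained.

The same stages are available as a subcommand CLI
(`inst/cli/perivasc simulate|geometry|normalize|profile|density|stats|report`),
each writing a manifest with its configuration, seed, and input hashes.

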