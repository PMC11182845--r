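Package: perivasc
Title: Vessel-Relative Quantification of Perivascular Tau in 3D Microscopy Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies phospho-tau and tangle pathology relative to individually
    segmented blood vessels in cleared-tissue 3D microscopy volumes. Computes
    anisotropy-aware Euclidean distance fields and arc-length parameterized
    centerlines for tubular vessel masks, harmonizes tau intensities across
    samples with a three-anchor piecewise-linear normalization, scores 10 micron
    vessel segments by surface-tau deciles, builds radial intensity profiles and
    per-vessel heatmaps, measures neuron and neurofibrillary-tangle densities in
    distance shells, and tests the association between vascular surface tau and
    the fraction of nearby tangle-bearing neurons with a repeated-measures
    ANOVA. Includes a seeded synthetic-scene generator emulating the statistical
    structure of cleared-tissue imaging volumes so the whole pipeline is
    testable without donor data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    rhdf5,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
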