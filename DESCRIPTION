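Package: fvheeplan
Title: Inverse Treatment Planning for Magnetically Focused Very High
    Energy Electron Beams
Version: 0.1.0
Authors@R:
    person("fvheeplan", "developers", email = "fvheeplan@example.org",
           role = c("aut", "cre"))
Description: Research toolkit for inverse treatment planning with
    magnetically focused very-high-energy electron (fVHEE) beams.
    Provides voxel phantoms with structure masks and synthetic planning
    scenarios, a purely geometric model of lens-focused beamlets, a
    simplified condensed-history Monte Carlo electron transport engine
    (CSDA energy loss plus Highland multiple scattering) with batch
    statistical uncertainty and a Fermi-Eyges analytic cross-check,
    hexagonal-close-packed 3D spot lattices covering the target plus
    margin, sparse dose-influence matrices, fluence-map optimization of
    nonnegative beamlet weights against dose and dose-volume objectives,
    plan normalization, and DVH-based plan evaluation (Dx%, Vd, mean
    dose, homogeneity index, Paddick conformity index) with comparison
    reports. A configuration-driven pipeline orchestrates the two-stage
    workflow (beamlet dose calculation, then inverse optimization) and a
    water-box beam characterization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    graphics,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
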