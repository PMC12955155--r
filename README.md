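# fvheeplan

Inverse treatment planning for magnetically focused very-high-energy
electron (fVHEE) beams, on synthetic voxel phantoms.

Very high energy electrons (50–250 MeV) reach deep-seated tumors and —
unlike photons — can be focused with magnetic lenses placed in front of
the patient. A converging beamlet concentrates dose around its
geometric focus, giving a peaked depth-dose analogous to a proton
Bragg peak but steered optically: shifting the focal length moves the
dose maximum in depth without changing the beam energy. `fvheeplan` is
a research toolkit for studying treatment planning with such beams. It
is aimed at medical-physics researchers who want a fully specified,
testable model of the whole planning chain rather than clinical-grade
physics.

## What the package computes

The workflow has two stages:

1. **Beamlet dose calculation.** Focal spots are arranged on a
   hexagonal-close-packed 3D lattice with nearest-neighbor distance
   *k*, covering the planning target volume (PTV) expanded by a margin
   *m*; the lattice is shared by all gantry angles. Each (beam, spot)
   pair is a beamlet: rays enter uniformly over a lens aperture of
   radius 5 cm and converge to a focal spot with 1 cm geometric fluence
   FWHM. Dose is computed by a condensed-history Monte Carlo engine
   (CSDA energy loss, Highland multiple scattering
   θ₀ = 13.6 MeV/(βcp)·√t·(1+0.038 ln t), bremsstrahlung escape
   approximation, batch uncertainty) and assembled into a sparse
   dose-influence matrix **A** with dose(w) = **A**·w.
2. **Inverse optimization and evaluation.** Nonnegative beamlet weights
   minimize F(w) = Σₒ pₒ/|Vₒ| Σᵢ e²ₒᵢ (uniform / max-dose / min-dose /
   mean-dose / DVH-max penalties) by projected gradient descent with
   Armijo backtracking. The plan is rescaled so D95% or D50% of the PTV
   equals the prescription, then evaluated with exact DVHs, Dx%, Vd,
   mean dose, homogeneity index HI = (D2%−D98%)/D50% and Paddick
   conformity index CI = |TV∩PIV|²/(|TV|·|PIV|).

Seven case templates (B, H, L1, L2, P1, P2, F) carry published per-case
beam angles, margins (0.5 / 0.25 cm), spacing factors (0.36 / 0.46 cm),
prescriptions and normalization modes; they are applied to synthetic
cylindrical phantoms (lateral, central or bilateral PTV/OAR geometry)
standing in for clinical CTs that are not distributed. See the methods
vignette (`vignettes/fvhee-methods.Rmd`) for the model details, design
decisions and limitations.

## Worked example

A fast demonstration plan — the femoral-head-like template (46.5 Gy in
10 fractions, D50 normalization) on the synthetic lateral scenario,
with three beams chosen to avoid the contralateral organ at risk:

```r
library(fvheeplan)
cfg <- list(case = "F", scenario = "lateral",
            phantom = list(voxel_size = 0.5, ptv_radius = 1.5),
            beams = list(angles = c(-45, 0, 45)),
            transport = list(n_histories = 2000),
            optimization = list(max_iter = 800, tol = 1e-8),
            seed = 11, out_dir = "run_F_lateral")
res <- run_pipeline(cfg)
print(res$lattice)
print(res$plan)
```

prints

```
spot_lattice: 231 spots, k = 0.46 cm, m = 0.25 cm
plan: 693 beamlets, objective 56.2003 after 800 iterations, scale 1.004
PTV  V95 = 100.0 %   D2 = 48.8 Gy   HI = 0.070   CI = 0.45
contralateral OAR  D2 = 0.00 Gy   Dmean = 0.000 Gy
```

Reading: 231 focal spots cover PTV⊕m; with 3 gantry angles that is 693
beamlets. After optimization and D50 normalization the whole PTV
receives at least 95% of the 46.5 Gy prescription (V95 = 100%), the
PTV dose is homogeneous (HI = 0.07) and the contralateral OAR is
essentially untouched — the directional-sparing behaviour that makes
laterally located targets favourable for this modality. Artifacts
(config with provenance, spot list, influence-matrix container, plan
weights, dose volume in NRRD, metrics and report) are written to
`run_F_lateral/`. A command-line front end with `run` and
`characterize` subcommands is installed at `inst/cli/fvhee.R`.

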