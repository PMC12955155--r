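---
title: "Methods: focused-VHEE beam modelling, dose calculation and inverse planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: focused-VHEE beam modelling, dose calculation and inverse planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model overview

`fvheeplan` implements an inverse treatment-planning workflow for
magnetically focused very-high-energy electron (fVHEE) beams on voxel
phantoms. Very high energy electrons (50–250 MeV) penetrate deeply and,
unlike photons, can be manipulated with magnetic lenses: a converging
beamlet produces a dose maximum near its geometric focus, analogous to a
proton Bragg peak but achieved by optics rather than by stopping power.
The package covers the full two-stage workflow:

1. **Beamlet dose calculation.** A lattice of focal spots covering the
   planning target volume (PTV) plus a margin is irradiated from each
   configured gantry angle; each (beam, spot) pair is one *beamlet*
   whose dose distribution is computed by Monte Carlo transport and
   stored as one column of a sparse dose-influence matrix.
2. **Inverse optimization.** Nonnegative beamlet weights are optimized
   against quadratic dose and dose-volume objectives (fluence-map
   optimization), the plan is normalized to the prescription, and
   evaluated with DVH metrics (Dx%, Vd, mean dose, homogeneity index,
   Paddick conformity index).

All coordinates are world centimetres, right-handed, origin at the
isocenter; x is lateral, +y anterior, z longitudinal. A voxel's world
position is its center. Gantry angle $\theta$ (table fixed at 0°) puts
the source direction at $s(\theta) = (\sin\theta, \cos\theta, 0)$; the
beam travels along $-s$.

# The geometric beam model

The focusing optics are modelled *purely geometrically* — no
electromagnetic lens simulation. A beamlet is defined by its beam
direction, the world position of its focal spot, the lens aperture
radius $R$ (default 5 cm), the lens-to-isocenter distance $L$, and the
geometric fluence FWHM $w$ at the focus (default 1 cm). Phase space is
sampled as:

* entry points uniform over the lens disc of radius $R$ — the aperture
  intensity profile is not specified by the physical design we emulate,
  and a uniform disc is the least-informative choice;
* each ray aimed at the focal spot displaced by a 2D isotropic Gaussian
  with $\sigma = w/\sqrt{8\ln 2}$ in the focal plane.

Because rays intersect the focal plane exactly at their Gaussian
targets, the vacuum fluence FWHM at the focus equals $w$ *by
construction*, which makes the nominal 1 cm spot size directly
verifiable (acceptance target t1). The focal length of a spot is
$f = L + d$, where $d$ is the signed distance from the isocenter plane
to the spot along the beam axis. Real quadrupole optics focus in one
transverse plane while defocusing in the other; symmetric focusing is
an idealization inherited from the design we model. The beam is
monoenergetic (default 250 MeV) with no upstream divergence.

$L$ defaults to 50 cm for planning geometries and is configurable per
beam; the water-box characterization uses a lens 7 cm before the
phantom surface. Whether the nominal spot FWHM refers to fluence or
dose is ambiguous in the source material; we take it as *fluence*.

# Monte Carlo transport engine

The engine is a deliberately simplified condensed-history transport,
specified completely so its behaviour is testable — it is a documented
stand-in for a general-purpose code (EGSnrc-class physics is out of
scope). Per step of fixed length $\Delta s$ (default 1 mm) in a voxel
of density $\rho$:

* collisional loss $S_{col}(E)\,\rho\,\Delta s$ is deposited in the
  current voxel (CSDA);
* radiative loss $S_{rad}(E)\,\rho\,\Delta s$ is removed without local
  deposition — bremsstrahlung photons are assumed to escape;
* the direction receives two independent Gaussian kicks with the
  Highland sigma
  $\theta_0 = \frac{13.6\,\mathrm{MeV}}{\beta c p}\sqrt{t}\,
  (1 + 0.038 \ln t)$, $t = \rho\,\Delta s / X_0$, $X_0 = 36.08$ g/cm²;
* the history ends when $E \le E_{cut}$ (default 2 MeV; the residual is
  deposited locally) or on phantom exit.

Stopping powers are tabulated for water on a 0.5–300 MeV grid
(log-log interpolated) and scaled by mass density only; there is no
Z-dependent correction, no secondary-particle transport, and no nuclear
interactions. Energy bookkeeping (collisional + sub-cutoff + radiative
+ escaped = input) closes to numerical precision and is enforced by a
property test at 1e-6 relative.

Statistical uncertainty uses the batch method: histories are split into
20 contiguous batches and the per-voxel relative sigma of the batch
mean is reported. The headline operating point — 10⁶ histories per
beamlet keeping the mean relative uncertainty below 1% over voxels
above 50% of the maximum dose, on 2.5 mm voxels — is acceptance target
t2. Nearest-voxel deposition with a fixed 1 mm step tolerates boundary
crossings within a step; the bias shrinks with $\Delta s$, which is
configurable.

A Fermi–Eyges analytic model serves as an independent oracle for
lateral spread in homogeneous water:
$\sigma^2(z) = \sigma_{geom}^2(z) + A_2(z)$ with
$A_2(z) = \int_0^z T(z')(z-z')^2\,dz'$ and the Highland scattering
power $T$ evaluated at the engine's step size so both share the same
logarithmic correction. The geometric envelope of the focused bundle is
$\sigma_{geom}^2 = (R^2/4)(1-\ell/f)^2 + \sigma_w^2(\ell/f)^2$ per
transverse axis. MC and analytic sigmas agree within 10% down to 10 cm
depth in water (property test).

# Spot lattice

The "diamond-like" 3D spot pattern is realized as hexagonal close
packing with nearest-neighbor distance $k$: in-layer hexagonal rows
(row pitch $k\sqrt{3}/2$, alternate rows offset $k/2$) stacked with
layer pitch $k\sqrt{2/3}$ and ABAB lateral offset. The lattice is
anchored at the PTV centroid and a candidate is retained iff its
position lies inside the PTV expanded by the margin $m$ (exact
Euclidean distance transform on voxel centers, anisotropic-spacing
correct). The lattice is generated once and shared by all beam
directions; each beam only changes the per-spot focal length. The
detailed placement rule of the original workflow is not public; this
construction is our own choice, consistent with the hexagonal
per-layer motivation and a single scalar spacing factor, and its
nearest-neighbor distance and pruning behaviour are property-tested
against a brute-force enumerator.

# Inverse optimization

The objective is a weighted sum of per-structure mean-squared penalties
$F(w) = \sum_o \frac{p_o}{|V_o|}\sum_{i\in V_o} e_{o,i}^2$ with
one-sided terms for max/min dose, a two-sided `uniform` target term, a
once-per-structure mean-dose term, and a DVH-max term that penalizes
only the voxels exceeding the dose limit beyond the allowed volume
fraction (smallest excesses above quota; the hottest allowed fraction
is spared — re-selected every iteration, hence non-convex). The exact
clinical objective catalogue of the original optimizer is not public;
these standard one-sided quadratics are a documented substitution.

The solver is projected gradient descent with Armijo backtracking and
projection onto $w \ge 0$: accepted objective values are monotone
non-increasing, iterates stay feasible, and the run is deterministic.
Initial weights are uniform, scaled so the mean PTV dose matches the
first PTV objective's reference. On toy problems with at most three
beamlets the solver matches an exhaustive grid search within 1%
(property test). Because the dose operator is linear, prescription
normalization is an exact global rescaling
$s = D_{pres} / D_{mode}(\mathrm{PTV})$ with mode D95 or D50.

# Plan evaluation

DVHs are exact (sorting-based, unbinned). $D_{x\%}$ interpolates
linearly between adjacent sorted doses; $V_d$ counts voxels at or above
the threshold. The homogeneity index uses the ICRU-83 form
$(D_{2\%}-D_{98\%})/D_{50\%}$ — the source material leaves the formula
blank, and published magnitudes are consistent with this choice. The
Paddick conformity index is
$|TV\cap PIV|^2 / (|TV|\,|PIV|)$ with the prescription isodose level
defaulting to 100% of $D_{pres}$ (95% available as an option; the
original level is unstated). All metrics are property-tested against
brute-force counting.

# Synthetic phantoms: what they emulate and what they do not

No patient CTs are distributed with the workflow we reimplement, so the
seven shipped case templates (B, H, L1, L2, P1, P2, F — carrying the
published beam angles, margin, spacing factor, prescription and
normalization mode) are applied to *synthetic* cylindrical water
phantoms with spherical PTVs:

* **lateral** — PTV ≥ 3 cm off-axis with a mirrored contralateral OAR,
  emulating the peripheral-lung / femoral-head geometry where beam
  directions can avoid the OAR entirely;
* **central** — PTV on the axis with anterior and posterior rods
  abutting it, emulating the prostate-type geometry in which OARs cap
  two opposing beam directions;
* **bilateral** — a lateral PTV with rod OARs on both sides.

Defaults: body radius 8 cm, length 16 cm, PTV radius 1.5 cm (≈14 cm³,
the order of the smaller clinical targets), 2.5 mm voxels — values a
planning study on pelvic/thoracic-scale anatomy would call realistic.
These phantoms preserve the *directional* structure of the planning
problem (which beam angles are blocked by OARs) but none of the
heterogeneity, contour complexity, or CT calibration of real anatomy.
A green planning test therefore establishes that the pipeline
optimizes, normalizes and evaluates correctly and that directional
sparing behaves as expected — it does not reproduce any published
per-patient DVH value, and the package deliberately asserts orderings
(e.g. OAR dose with avoiding vs. through-OAR beams), not clinical
numbers.

# Numerical choices

* Step length 1 mm, energy cutoff 2 MeV, 20 batches; influence-matrix
  pruning at $\tau = 10^{-3}$ of each beamlet's maximum (retains
  ≥ 99% of the column sum).
* The global seed fans out to deterministic per-beamlet sub-seeds
  (31-bit LCG hash of beam and spot index), so the assembled influence
  matrix is identical regardless of computation order.
* Fast vs. characterization scale: demo plans use 10³–10⁴ histories
  per beamlet; the printed uncertainty operating point uses 10⁶.
* Dx interpolation is positively homogeneous, making D95/D50
  normalization exact to machine precision.
* Degenerate inputs are first-class: vacuum phantoms transport to zero
  dose (not an error), a vacuum characterization flags an undefined
  dose maximum, an empty prescription isodose volume returns CI = 0
  with a warning, and D50 = 0 flags the homogeneity index as NaN.

# Known limitations

* Physics: no secondary electrons, no bremsstrahlung photon transport
  (radiative energy is removed non-locally), Gaussian-only scattering
  (no large-angle tails), water-like media scaled by density only. The
  sub-1% uncertainty claim is engine-dependent and is tested under
  exactly these documented conditions.
* Optics: symmetric thin-lens focusing; no quadrupole asymmetry, no
  energy spread, no upstream emittance.
* Planning: single energy layer, one shared spot lattice for all
  beams, no robustness/motion analysis, no delivery-time model.
* I/O: NRRD only (no NIfTI codec in the dependency set); the influence
  matrix persists to a plain-text CSC container rather than HDF5.
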