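#' Transport configuration
#'
#' @param step step length Delta-s (cm), default 0.1. Deposition is
#'   nearest-voxel; the boundary-crossing bias shrinks with the step.
#' @param e_cut kinetic-energy cutoff (MeV), default 2; residual energy is
#'   deposited locally when a history falls below it.
#' @param n_histories number of primary histories, default 1e4 ("fast"
#'   demo scale; characterization-grade runs use 1e6).
#' @param n_batches batches for the statistical-uncertainty estimate,
#'   default 20, >= 2.
#' @param seed optional RNG seed applied before sampling/transport.
#' @return An object of class `transport_config`.
#' @export
transport_config <- function(step = 0.1, e_cut = 2, n_histories = 1e4,
                             n_batches = 20, seed = NULL) {
  if (step <= 0) stop("transport_config: step must be > 0")
  if (e_cut <= 0) stop("transport_config: e_cut must be > 0")
  if (n_batches < 2) stop("transport_config: n_batches must be >= 2")
  if (n_histories < 1) stop("transport_config: n_histories must be >= 1")
  structure(list(step = step, e_cut = e_cut,
                 n_histories = as.integer(n_histories),
                 n_batches = as.integer(n_batches), seed = seed),
            class = "transport_config")
}

#' Monte Carlo electron transport of a RaySet through a phantom
#'
#' Condensed-history transport with fixed step length: per step of length
#' `step` in density rho, the collisional loss `S_col(E) rho step` is
#' deposited in the current voxel, the radiative loss `S_rad(E) rho step`
#' is removed without local deposition (bremsstrahlung escape
#' approximation), and the direction receives two independent Gaussian
#' kicks with the Highland sigma
#' `theta0 = 13.6 MeV / (beta c p) * sqrt(t) * (1 + 0.038 ln t)`,
#' `t = rho step / X0`. A history ends below `e_cut` (residual deposited
#' locally) or on phantom exit. Per-voxel relative uncertainty comes from
#' the batch method over `n_batches` contiguous history blocks.
#'
#' @param phantom a [phantom()].
#' @param rays a `ray_set` (see [sample_phase_space()]); rays may start
#'   outside the phantom and are advanced to its boundary in vacuum.
#' @param cfg a [transport_config()]. `cfg$n_histories` is ignored here
#'   (the RaySet defines the histories); `cfg$seed`, if non-NULL, seeds
#'   the scattering RNG.
#' @return An object of class `dose_grid`: list with `grid`, `dose`
#'   (3D array, Gy per history per unit beamlet weight), `rel_unc`
#'   (3D array, relative sigma), `n_histories`, and `ledger` — the energy
#'   bookkeeping in MeV with components input, collisional, sub_cutoff,
#'   radiative, escaped.
#' @export
transport <- function(phantom, rays, cfg = transport_config()) {
  stopifnot(inherits(phantom, "phantom"), inherits(rays, "ray_set"))
  if (nrow(rays$pos) < 1) stop("transport: empty RaySet")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  g <- phantom$grid
  res <- transport_cpp(as.numeric(phantom$density), g$dims, g$origin,
                       g$spacing, rays$pos, rays$dir,
                       rays$energy, rays$weight,
                       water_stopping_powers()$energy,
                       water_stopping_powers()$s_col,
                       water_stopping_powers()$s_rad,
                       water_radiation_length(), cfg$step, cfg$e_cut,
                       cfg$n_batches)
  n_eff <- sum(rays$weight)
  vol <- grid_voxel_volume(g)
  mass_g <- as.numeric(phantom$density) * vol       # per-voxel mass
  dose <- numeric(length(mass_g))
  nz <- mass_g > 0
  dose[nz] <- res$edep[nz] / mass_g[nz] * MEV_PER_G_TO_GY / n_eff
  structure(list(grid = g,
                 dose = array(dose, dim = g$dims),
                 rel_unc = array(res$rel_unc, dim = g$dims),
                 n_histories = nrow(rays$pos),
                 ledger = res$ledger),
            class = "dose_grid")
}

#' Simulate one beamlet into a phantom
#'
#' Convenience wrapper: samples the phase space and transports it.
#'
#' @param phantom a [phantom()].
#' @param beamlet a [beamlet_spec()].
#' @param cfg a [transport_config()]; `n_histories` and `seed` are used.
#' @return a `dose_grid`.
#' @export
simulate_beamlet <- function(phantom, beamlet, cfg = transport_config()) {
  rays <- sample_phase_space(beamlet, cfg$n_histories, seed = cfg$seed)
  transport(phantom, rays, cfg)
}

#' Energy-conservation residual of a transport run
#'
#' `(collisional + sub_cutoff + radiative + escaped - input) / input`;
#' closes to numerical precision by construction of the engine and is the
#' engine's primary bookkeeping invariant.
#'
#' @param dg a `dose_grid` from [transport()].
#' @return signed relative residual.
#' @export
energy_balance <- function(dg) {
  l <- dg$ledger
  (l[["collisional"]] + l[["sub_cutoff"]] + l[["radiative"]] +
     l[["escaped"]] - l[["input"]]) / l[["input"]]
}

#' Mean relative uncertainty over high-dose voxels
#'
#' Averages the per-voxel relative statistical uncertainty over voxels
#' whose dose exceeds `frac` of the maximum dose — the standard Monte
#' Carlo dose-engine operating-point figure (reported in percent).
#'
#' @param dg a `dose_grid`.
#' @param frac dose threshold as a fraction of the maximum, default 0.5.
#' @return mean relative uncertainty in percent.
#' @export
mean_high_dose_uncertainty <- function(dg, frac = 0.5) {
  dmax <- max(dg$dose)
  if (dmax <= 0) stop("mean_high_dose_uncertainty: zero dose everywhere")
  sel <- dg$dose > frac * dmax
  100 * mean(dg$rel_unc[sel])
}
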