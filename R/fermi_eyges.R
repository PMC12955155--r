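#' Fermi-Eyges lateral-spread moment A2
#'
#' Second Fermi-Eyges moment of a scattering power profile for an
#' initially parallel, point-like beam entering the medium at depth 0:
#' `A2(z) = integral_0^z T(z') (z - z')^2 dz'` (cm^2). For constant T this
#' is the textbook `T z^3 / 3`.
#'
#' @param depths depths (cm) at which to evaluate.
#' @param T_fun scattering power (rad^2/cm): a constant or a function of
#'   depth.
#' @param step integration step (cm), default 0.01.
#' @return numeric vector of A2 values (cm^2).
#' @export
fermi_eyges_a2 <- function(depths, T_fun, step = 0.01) {
  if (!is.function(T_fun)) {
    Tconst <- T_fun
    T_fun <- function(z) rep(Tconst, length(z))
  }
  vapply(depths, function(z) {
    if (z <= 0) return(0)
    zz <- seq(step / 2, z, by = step)
    sum(T_fun(zz) * (z - zz)^2) * step
  }, numeric(1))
}

#' Highland scattering power of water at the engine's step size
#'
#' `T(E) = (13.6 / beta c p)^2 * (rho / X0) * (1 + 0.038 ln t)^2` with
#' `t = rho * step / X0`: the per-unit-length variance of the Monte Carlo
#' engine's Highland kicks, so the analytic model and the engine share the
#' same (step-dependent) logarithmic correction.
#'
#' @param E kinetic energy (MeV).
#' @param step the engine step (cm), default 0.1.
#' @param rho density (g/cm^3), default 1 (water).
#' @return scattering power (rad^2/cm).
#' @export
highland_scattering_power <- function(E, step = 0.1, rho = 1) {
  t <- rho * step / water_radiation_length()
  corr <- pmax(0, 1 + 0.038 * log(t))
  (13.6 / beta_pc(E))^2 * (rho / water_radiation_length()) * corr^2
}

# CSDA kinetic energy vs depth in water (total stopping power), from E0 at
# depth 0; returns a function of depth clamped at the cutoff.
csda_energy_profile <- function(E0, rho = 1, step = 0.01, e_min = 0.5) {
  sp <- water_stopping_powers()
  stot <- function(E) {
    exp(stats::approx(log(sp$energy), log(sp$s_col + sp$s_rad), log(E),
                      rule = 2)$y)
  }
  zmax <- 120
  n <- ceiling(zmax / step)
  Ez <- numeric(n + 1)
  Ez[1] <- E0
  for (i in seq_len(n)) {
    Ez[i + 1] <- max(e_min, Ez[i] - stot(max(Ez[i], e_min)) * rho * step)
  }
  zs <- (0:n) * step
  function(z) stats::approx(zs, Ez, pmin(z, zmax), rule = 2)$y
}

#' Analytic lateral sigma of a focused beamlet in homogeneous water
#'
#' Combines the vacuum geometric envelope of the focused bundle with the
#' Fermi-Eyges multiple-scattering spread, added in quadrature:
#' `sigma^2(z) = sigma_geom^2(z) + A2(z)`. The geometric envelope of a
#' uniform-disc aperture (radius R) aimed at Gaussian focal targets
#' (fluence FWHM w) at focal length f is, per transverse axis,
#' `sigma_geom^2 = (R^2/4) (1 - l/f)^2 + sigma_w^2 (l/f)^2` where `l` is
#' the distance from the lens plane. Energy degrades along depth via the
#' CSDA so the scattering power grows with depth.
#'
#' @param depths depths below the water surface (cm).
#' @param energy beam kinetic energy at the surface (MeV).
#' @param focal_length f, lens plane to focus (cm).
#' @param lens_to_surface distance lens plane to water surface (cm);
#'   must be < focal_length for a focus inside the medium.
#' @param lens_radius aperture radius (cm), default 5.
#' @param focal_fwhm geometric fluence FWHM at the focus (cm), default 1.
#' @param step Monte Carlo step length the Highland correction refers to
#'   (cm), default 0.1.
#' @param scattering_power override: NULL (water Highland, default), a
#'   constant (rad^2/cm), or 0 to disable scattering entirely.
#' @return data.frame with `depth`, `sigma`, `sigma_geom`, `sigma_mcs`
#'   (cm, per transverse axis).
#' @export
fermi_eyges_sigma <- function(depths, energy = 250, focal_length,
                              lens_to_surface, lens_radius = 5,
                              focal_fwhm = 1, step = 0.1,
                              scattering_power = NULL) {
  sig_w <- focal_fwhm / sqrt(8 * log(2))
  l <- lens_to_surface + depths
  sg2 <- (lens_radius^2 / 4) * (1 - l / focal_length)^2 +
    sig_w^2 * (l / focal_length)^2
  if (is.null(scattering_power)) {
    Ez <- csda_energy_profile(energy)
    T_fun <- function(z) highland_scattering_power(Ez(z), step = step)
  } else {
    T_fun <- scattering_power
  }
  a2 <- fermi_eyges_a2(depths, T_fun)
  data.frame(depth = depths,
             sigma = sqrt(sg2 + a2),
             sigma_geom = sqrt(sg2),
             sigma_mcs = sqrt(a2))
}
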