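#' Beam configuration for one gantry direction
#'
#' Describes the magnetic-lens geometry seen from one gantry angle. The
#' model is purely geometric: rays leave the circular lens aperture and
#' converge to a focal spot; no electromagnetic lens simulation.
#'
#' @param gantry_angle gantry angle theta in degrees (table fixed at 0).
#' @param lens_radius aperture radius R_lens (cm), default 5.
#' @param lens_to_iso distance L from the lens plane to the isocenter along
#'   the beam axis (cm), default 50; > 0.
#' @param energy beam kinetic energy (MeV), default 250.
#' @return An object of class `beam_config`.
#' @export
beam_config <- function(gantry_angle = 0, lens_radius = 5,
                        lens_to_iso = 50, energy = 250) {
  if (lens_radius <= 0) stop("beam_config: lens_radius must be > 0")
  if (lens_to_iso <= 0) stop("beam_config: lens_to_iso must be > 0")
  if (energy <= 0) stop("beam_config: energy must be > 0")
  structure(list(gantry_angle = gantry_angle, lens_radius = lens_radius,
                 lens_to_iso = lens_to_iso, energy = energy),
            class = "beam_config")
}

#' Gantry geometry for an angle
#'
#' Returns the rigid beam-frame geometry for gantry angle theta with the
#' treatment table fixed at 0 degrees. The source direction (isocenter
#' toward source) is `s(theta) = (sin theta, cos theta, 0)`; the beam
#' travels along `-s`. `e1`/`e2` span the transverse plane (e2 is the
#' longitudinal axis z), so `(e1, e2, beam_dir)` is orthonormal.
#'
#' @param gantry_angle angle in degrees.
#' @return list with `source_dir`, `beam_dir`, `e1`, `e2`.
#' @export
gantry_transform <- function(gantry_angle) {
  th <- gantry_angle * pi / 180
  s <- c(sin(th), cos(th), 0)
  list(source_dir = s,
       beam_dir = -s,
       e1 = c(cos(th), -sin(th), 0),
       e2 = c(0, 0, 1))
}

#' Focused beamlet specification
#'
#' One beamlet: a beam direction plus the world position of the focal
#' spot. The focal length is the distance from the lens plane to the spot
#' along the beam axis; the geometric focal-spot size at the focus is
#' `focal_fwhm` (fluence FWHM, cm).
#'
#' @param beam a [beam_config()].
#' @param spot length-3 world position of the focal point (cm).
#' @param focal_fwhm geometric fluence FWHM at the focus (cm), default 1.
#' @return An object of class `beamlet_spec` with the derived
#'   `focal_length` (via [focal_length_for_spot()]).
#' @export
beamlet_spec <- function(beam, spot, focal_fwhm = 1) {
  stopifnot(inherits(beam, "beam_config"))
  if (focal_fwhm <= 0) stop("beamlet_spec: focal_fwhm must be > 0")
  f <- focal_length_for_spot(beam, spot)
  structure(list(beam = beam, spot = as.numeric(spot),
                 focal_length = f, focal_fwhm = focal_fwhm),
            class = "beamlet_spec")
}

#' Focal length for a spot position
#'
#' `f = L + (signed distance from the isocenter plane to the spot along
#' the beam axis)`, positive downstream. The spot must lie strictly
#' downstream of the lens plane (f > 0).
#'
#' @param beam a [beam_config()].
#' @param spot length-3 world position (cm).
#' @return focal length f (cm).
#' @export
focal_length_for_spot <- function(beam, spot) {
  gt <- gantry_transform(beam$gantry_angle)
  f <- beam$lens_to_iso + sum((as.numeric(spot)) * gt$beam_dir)
  if (f <= 0)
    stop("focal_length_for_spot: spot lies upstream of the lens plane")
  f
}

#' World position of the lens-plane center
#' @param beam a [beam_config()].
#' @keywords internal
lens_center <- function(beam) {
  gantry_transform(beam$gantry_angle)$source_dir * beam$lens_to_iso
}

#' Sample the beamlet phase space (a RaySet)
#'
#' Entry points are uniform over the lens disc (radius `R_lens`); each ray
#' is aimed at the focal spot displaced by a 2D isotropic Gaussian in the
#' focal plane with fluence FWHM `focal_fwhm` (sigma = FWHM / sqrt(8 ln 2)).
#' The beam is monoenergetic with unit statistical weights. In vacuum the
#' bundle therefore reproduces the nominal geometric FWHM at the focus by
#' construction.
#'
#' @param b a [beamlet_spec()].
#' @param n number of rays, >= 1.
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the RaySet is reproducible.
#' @return An object of class `ray_set`: list with `pos` (n x 3), `dir`
#'   (n x 3, unit rows), `energy`, `weight` (length n).
#' @export
sample_phase_space <- function(b, n, seed = NULL) {
  stopifnot(inherits(b, "beamlet_spec"))
  if (n < 1) stop("sample_phase_space: n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  gt <- gantry_transform(b$beam$gantry_angle)
  lc <- lens_center(b$beam)

  r <- b$beam$lens_radius * sqrt(stats::runif(n))
  phi <- stats::runif(n, 0, 2 * pi)
  a1 <- r * cos(phi)
  a2 <- r * sin(phi)
  pos <- cbind(lc[1] + a1 * gt$e1[1] + a2 * gt$e2[1],
               lc[2] + a1 * gt$e1[2] + a2 * gt$e2[2],
               lc[3] + a1 * gt$e1[3] + a2 * gt$e2[3])

  sig <- b$focal_fwhm / sqrt(8 * log(2))
  d1 <- stats::rnorm(n, 0, sig)
  d2 <- stats::rnorm(n, 0, sig)
  tgt <- cbind(b$spot[1] + d1 * gt$e1[1] + d2 * gt$e2[1],
               b$spot[2] + d1 * gt$e1[2] + d2 * gt$e2[2],
               b$spot[3] + d1 * gt$e1[3] + d2 * gt$e2[3])
  dir <- tgt - pos
  dir <- dir / sqrt(rowSums(dir^2))
  structure(list(pos = pos, dir = dir,
                 energy = rep(b$beam$energy, n), weight = rep(1, n)),
            class = "ray_set")
}

#' Propagate a RaySet in vacuum to a plane
#'
#' Intersects every ray with the plane through `point` with normal
#' `normal` (straight-line propagation, no medium).
#'
#' @param rays a `ray_set`.
#' @param point,normal plane definition (world cm).
#' @return n x 3 matrix of intersection points.
#' @export
propagate_to_plane <- function(rays, point, normal) {
  normal <- normal / sqrt(sum(normal^2))
  num <- as.numeric((matrix(point, nrow(rays$pos), 3, byrow = TRUE) -
                       rays$pos) %*% normal)
  den <- as.numeric(rays$dir %*% normal)
  t <- num / den
  rays$pos + rays$dir * t
}

#' Estimate the FWHM of a 1D sample by histogramming
#'
#' Bins the sample, finds the peak, and locates the half-maximum crossings
#' by linear interpolation between bin centers.
#'
#' @param x numeric sample (e.g. lateral ray positions at a plane).
#' @param bin bin width; default chooses ~80 bins over the central 99.8%.
#' @return FWHM estimate in the units of `x`.
#' @export
estimate_fwhm <- function(x, bin = NULL) {
  if (is.null(bin)) {
    rng <- stats::quantile(x, c(0.001, 0.999), names = FALSE)
    bin <- diff(rng) / 80
  }
  brk <- seq(min(x) - bin, max(x) + bin, by = bin)
  h <- graphics::hist(x, breaks = brk, plot = FALSE)
  y <- h$counts
  cx <- h$mids
  imax <- which.max(y)
  half <- y[imax] / 2
  left <- NA_real_
  if (imax > 1) {
    for (i in seq(imax - 1, 1)) { # nearest crossing left of the peak
      if (y[i] <= half && y[i + 1] > half) {
        left <- cx[i] + (half - y[i]) / (y[i + 1] - y[i]) * (cx[i + 1] - cx[i])
        break
      }
    }
  }
  right <- NA_real_
  if (imax < length(y)) {
    for (i in seq(imax, length(y) - 1)) { # nearest crossing right of the peak
      if (y[i] > half && y[i + 1] <= half) {
        right <- cx[i] + (y[i] - half) / (y[i] - y[i + 1]) * (cx[i + 1] - cx[i])
        break
      }
    }
  }
  if (!is.finite(left) || !is.finite(right))
    stop("estimate_fwhm: could not bracket the half maximum")
  right - left
}
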