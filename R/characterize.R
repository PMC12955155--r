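#' Water-box characterization of one beamlet
#'
#' Simulates the beamlet into a homogeneous water phantom and extracts the
#' central-axis depth-dose curve (dose averaged over a central cylinder)
#' and lateral profiles along x at the depth of maximum dose and 5 cm and
#' 10 cm beyond it. Requires gantry angle 0 (beam along -y); depth is
#' measured from the upstream phantom face.
#'
#' @param beamlet a [beamlet_spec()] with gantry angle 0.
#' @param phantom a homogeneous water [phantom()].
#' @param cfg a [transport_config()].
#' @param axis_radius radius of the central averaging cylinder (cm),
#'   default 0.5.
#' @param out_dir optional directory; when given, writes
#'   `depth_dose.csv` and `lateral_profiles.csv`.
#' @return An object of class `beam_characterization`: list with
#'   `depth_dose` (depth, dose, rel_unc), `profiles` (offset_cm, dose,
#'   depth_label), `dmax_depth`, and the underlying `dose_grid`.
#' @export
characterize <- function(beamlet, phantom, cfg = transport_config(),
                         axis_radius = 0.5, out_dir = NULL) {
  stopifnot(inherits(beamlet, "beamlet_spec"))
  if (abs(beamlet$beam$gantry_angle) > 1e-9)
    stop("characterize: water-box characterization expects gantry angle 0")
  dg <- simulate_beamlet(phantom, beamlet, cfg)
  g <- phantom$grid
  if (max(dg$dose) <= 0)
    stop("characterize: zero dose everywhere (vacuum phantom?); ",
         "depth of maximum is undefined")

  xs <- grid_axis_centers(g, 1)
  ys <- grid_axis_centers(g, 2)
  zs <- grid_axis_centers(g, 3)
  y_front <- max(ys) + g$spacing[2] / 2 # upstream face (beam enters from +y)
  depth <- y_front - ys

  incyl <- outer(xs^2, zs^2, "+") <= axis_radius^2 # nx x nz selector
  dd <- vapply(seq_along(ys), function(j) {
    sl <- dg$dose[, j, ] # nx x nz
    mean(sl[incyl])
  }, numeric(1))
  du <- vapply(seq_along(ys), function(j) {
    sl <- dg$rel_unc[, j, ]
    mean(sl[incyl])
  }, numeric(1))
  ord <- order(depth)
  depth_dose <- data.frame(depth = depth[ord], dose = dd[ord],
                           rel_unc = du[ord])

  jmax <- which.max(dd)
  dmax_depth <- depth[jmax]
  kz <- which.min(abs(zs)) # slice through the beam axis
  prof <- do.call(rbind, lapply(c(0, 5, 10), function(extra) {
    dtarget <- dmax_depth + extra
    jj <- which.min(abs(depth - dtarget))
    if (abs(depth[jj] - dtarget) > g$spacing[2]) return(NULL)
    data.frame(offset_cm = xs, dose = dg$dose[, jj, kz],
               depth_cm = depth[jj],
               depth_label = sprintf("dmax%+g cm", extra))
  }))

  res <- structure(list(depth_dose = depth_dose, profiles = prof,
                        dmax_depth = dmax_depth, dose_grid = dg),
                   class = "beam_characterization")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(depth_dose, file.path(out_dir, "depth_dose.csv"),
                     row.names = FALSE)
    utils::write.csv(prof, file.path(out_dir, "lateral_profiles.csv"),
                     row.names = FALSE)
  }
  res
}

#' Monte Carlo lateral sigma versus depth
#'
#' Dose-weighted standard deviation of the lateral (x) coordinate in each
#' depth slice of a `dose_grid` from a gantry-0 beamlet — the engine-side
#' counterpart of [fermi_eyges_sigma()].
#'
#' @param dg a `dose_grid`.
#' @param depths depths (cm) below the upstream face at which to report.
#' @return data.frame with `depth` and `sigma` (cm).
#' @export
mc_lateral_sigma <- function(dg, depths) {
  g <- dg$grid
  xs <- grid_axis_centers(g, 1)
  ys <- grid_axis_centers(g, 2)
  y_front <- max(ys) + g$spacing[2] / 2
  slice_depth <- y_front - ys
  sig <- vapply(depths, function(d) {
    j <- which.min(abs(slice_depth - d))
    sl <- dg$dose[, j, ]
    wsum <- sum(sl)
    if (wsum <= 0) return(NA_real_)
    wx <- rowSums(sl) / wsum
    mu <- sum(wx * xs)
    sqrt(sum(wx * (xs - mu)^2))
  }, numeric(1))
  data.frame(depth = depths, sigma = sig)
}
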