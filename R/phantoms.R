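#' Voxel phantom
#'
#' A `phantom` couples a [voxel_grid()] with a per-voxel mass-density array
#' (g/cm^3). Density is the only material property the transport engine
#' uses: all media are treated as density-scaled water.
#'
#' @param grid a [voxel_grid()].
#' @param density 3D numeric array matching `grid$dims`; values >= 0.
#' @return An object of class `phantom`.
#' @export
phantom <- function(grid, density) {
  stopifnot(inherits(grid, "voxel_grid"))
  density <- as.array(density)
  if (!identical(dim(density), as.integer(grid$dims)))
    stop("phantom: density array shape must equal grid dims")
  if (any(density < 0) || any(!is.finite(density)))
    stop("phantom: density must be finite and >= 0")
  structure(list(grid = grid, density = density), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("phantom\n")
  print(x$grid)
  cat(sprintf("  density range: [%.4g, %.4g] g/cm^3, mass %.6g g\n",
              min(x$density), max(x$density), phantom_mass(x)))
  invisible(x)
}

#' Total phantom mass (g)
#'
#' Sum of density times voxel volume; exact for uniform phantoms.
#' @param p a [phantom()].
#' @export
phantom_mass <- function(p) sum(p$density) * grid_voxel_volume(p$grid)

#' Structure set: named binary masks on a shared grid
#'
#' Masks "PTV" (planning target volume) and "BODY" are required for
#' planning; the PTV must be contained in BODY and be nonempty.
#'
#' @param grid a [voxel_grid()].
#' @param masks named list of logical 3D arrays matching `grid$dims`.
#' @param require_planning enforce PTV/BODY presence and PTV subset BODY
#'   (default TRUE).
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(grid, masks, require_planning = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"), is.list(masks))
  if (is.null(names(masks)) || any(names(masks) == ""))
    stop("structure_set: every mask must be named")
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m)) stop("structure_set: mask '", nm, "' must be logical")
    if (!identical(dim(m), as.integer(grid$dims)))
      stop("structure_set: mask '", nm, "' does not match grid dims")
  }
  if (require_planning) {
    if (!all(c("PTV", "BODY") %in% names(masks)))
      stop("structure_set: masks 'PTV' and 'BODY' are required")
    if (!any(masks$PTV)) stop("structure_set: PTV is empty")
    if (any(masks$PTV & !masks$BODY))
      stop("structure_set: PTV must be contained in BODY")
  }
  structure(list(grid = grid, masks = masks), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("structure_set:\n")
  for (nm in names(x$masks))
    cat(sprintf("  %-16s %d voxels\n", nm, sum(x$masks[[nm]])))
  invisible(x)
}

#' Case template: beam/beamlet setup for one planning case
#'
#' Mirrors the per-case planning parameters: beam angles, fixed beam
#' energy, lattice margin m and spacing factor k, prescription and
#' normalization mode (D95 or D50).
#'
#' @param name short case label.
#' @param beam_angles gantry angles in degrees.
#' @param energy beam kinetic energy (MeV), > 0.
#' @param margin uniform PTV expansion m (cm) for spot placement, >= 0.
#' @param spacing_factor lattice nearest-neighbor distance k (cm), > 0.
#' @param d_pres total prescription dose (Gy), > 0.
#' @param n_fractions number of fractions (informational).
#' @param normalization "D95" or "D50": which PTV percentile is scaled to
#'   100% of the prescription.
#' @return An object of class `case_template`.
#' @export
case_template <- function(name, beam_angles, energy = 250, margin = 0.5,
                          spacing_factor = 0.36, d_pres, n_fractions = 1,
                          normalization = c("D95", "D50")) {
  normalization <- match.arg(normalization)
  stopifnot(length(beam_angles) >= 1)
  if (margin < 0) stop("case_template: margin m must be >= 0")
  if (spacing_factor <= 0) stop("case_template: spacing factor k must be > 0")
  if (d_pres <= 0) stop("case_template: prescription dose must be > 0")
  if (energy <= 0) stop("case_template: energy must be > 0")
  structure(list(name = name, beam_angles = as.numeric(beam_angles),
                 energy = energy, margin = margin,
                 spacing_factor = spacing_factor, d_pres = d_pres,
                 n_fractions = n_fractions, normalization = normalization),
            class = "case_template")
}

#' Shipped case templates
#'
#' Seven templates (B, H, L1, L2, P1, P2, F) carrying the published
#' per-case beam angles, margin m, spacing factor k, prescription and
#' normalization mode. They are applied to *synthetic* phantom scenarios
#' (see [make_planning_case()]); the clinical CT anatomies are not
#' distributed.
#'
#' @param name optional single template name; omit for the full list.
#' @return A `case_template`, or a named list of all seven.
#' @export
case_templates <- function(name = NULL) {
  tpl <- list(
    B  = case_template("B",  c(-130, -90, 130), margin = 0.5,
                       spacing_factor = 0.36, d_pres = 12, n_fractions = 2,
                       normalization = "D95"),
    H  = case_template("H",  c(-20, 0, 30, 90), margin = 0.5,
                       spacing_factor = 0.36, d_pres = 50, n_fractions = 25,
                       normalization = "D95"),
    L1 = case_template("L1", c(-150, -90, 150, 180), margin = 0.5,
                       spacing_factor = 0.36, d_pres = 60, n_fractions = 30,
                       normalization = "D50"),
    L2 = case_template("L2", c(-130, -90, 130, 180), margin = 0.5,
                       spacing_factor = 0.36, d_pres = 60, n_fractions = 30,
                       normalization = "D50"),
    P1 = case_template("P1", c(-150, -110, -20, 20, 110, 150), margin = 0.5,
                       spacing_factor = 0.46, d_pres = 60, n_fractions = 30,
                       normalization = "D50"),
    P2 = case_template("P2", c(-150, -110, -20, 20, 110, 150), margin = 0.5,
                       spacing_factor = 0.46, d_pres = 60, n_fractions = 30,
                       normalization = "D50"),
    F  = case_template("F",  c(-25, 0, 25, 90, 180), margin = 0.25,
                       spacing_factor = 0.46, d_pres = 46.5, n_fractions = 10,
                       normalization = "D50")
  )
  if (is.null(name)) return(tpl)
  if (!name %in% names(tpl))
    stop("unknown case template '", name, "'")
  tpl[[name]]
}

#' Uniform water-box phantom
#'
#' @param side_lengths length-3 box side lengths (cm), > 0.
#' @param voxel_size scalar or length-3 voxel size (cm); should divide the
#'   box sides within rounding.
#' @param center world position of the box center (cm); default isocenter.
#' @return A [phantom()] with uniform density 1.0 g/cm^3. The BODY mask is
#'   the full box (attach via [structure_set()] if needed).
#' @export
make_water_box <- function(side_lengths, voxel_size, center = c(0, 0, 0)) {
  side_lengths <- as.numeric(side_lengths)
  if (length(side_lengths) == 1L) side_lengths <- rep(side_lengths, 3L)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(side_lengths <= 0) || any(voxel_size <= 0))
    stop("make_water_box: sizes must be positive")
  dims <- as.integer(round(side_lengths / voxel_size))
  dims[dims < 1L] <- 1L
  # first voxel center sits half a voxel inside the box face
  origin <- center - side_lengths / 2 + voxel_size / 2
  g <- voxel_grid(origin, voxel_size, dims)
  phantom(g, array(1.0, dim = dims))
}

#' Expand a binary mask by a Euclidean margin
#'
#' Uniform expansion realized with an exact Euclidean distance transform on
#' voxel centers (anisotropic-spacing correct), not a structuring-element
#' dilation: the result contains every voxel whose center lies within `m`
#' cm of some voxel center of the input mask.
#'
#' @param mask logical 3D array.
#' @param m margin (cm), >= 0.
#' @param spacing per-axis voxel size (cm), scalar or length-3.
#' @return logical array of the same shape; always a superset of `mask`.
#' @export
expand_mask <- function(mask, m, spacing) {
  if (length(m) != 1L || !is.finite(m) || m < 0)
    stop("expand_mask: margin m must be a single number >= 0")
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (m == 0) return(mask)
  d2 <- edt_squared_cpp(mask, dim(mask), as.numeric(spacing))
  out <- array(d2 <= m^2 + 1e-12, dim = dim(mask))
  out
}

#' Synthetic planning case
#'
#' Builds a cylindrical water "patient" phantom (axis along z) with a
#' spherical PTV and rod/shell organs at risk, standing in for clinical CT
#' anatomies that are not distributed:
#' \describe{
#'   \item{lateral}{PTV offset laterally from the axis (>= 3 cm), with a
#'     disjoint "contralateral" spherical OAR mirrored across the axis —
#'     emulates a peripheral lung or femoral-head geometry.}
#'   \item{central}{PTV on the axis with anterior and posterior rod OARs
#'     abutting the PTV surface (the posterior rod is rectum-like) —
#'     emulates a prostate-type geometry where OARs cap two opposing beam
#'     directions.}
#'   \item{bilateral}{lateral PTV with rod OARs on both lateral sides.}
#' }
#'
#' @param template a [case_template()].
#' @param scenario one of "lateral", "central", "bilateral".
#' @param body_radius,body_length cylinder radius/length (cm).
#' @param ptv_radius PTV sphere radius (cm).
#' @param voxel_size isotropic voxel size (cm), default 0.25.
#' @return list with elements `phantom` (a [phantom()]) and `structures`
#'   (a [structure_set()]).
#' @export
make_planning_case <- function(template,
                               scenario = c("lateral", "central", "bilateral"),
                               body_radius = 8, body_length = 16,
                               ptv_radius = 1.5, voxel_size = 0.25) {
  stopifnot(inherits(template, "case_template"))
  scenario <- match.arg(scenario)

  side <- c(2 * body_radius + 1, 2 * body_radius + 1, body_length)
  p <- make_water_box(side, voxel_size)
  g <- p$grid
  xs <- grid_axis_centers(g, 1); ys <- grid_axis_centers(g, 2)
  zs <- grid_axis_centers(g, 3)
  X <- array(rep(xs, times = g$dims[2] * g$dims[3]), dim = g$dims)
  Y <- array(rep(rep(ys, each = g$dims[1]), times = g$dims[3]), dim = g$dims)
  Z <- array(rep(zs, each = g$dims[1] * g$dims[2]), dim = g$dims)

  body <- (X^2 + Y^2) <= body_radius^2
  dens <- array(0, dim = g$dims)
  dens[body] <- 1.0
  p <- phantom(g, dens)

  sphere <- function(c0, r) (X - c0[1])^2 + (Y - c0[2])^2 + (Z - c0[3])^2 <= r^2
  rod <- function(c0, r) (X - c0[1])^2 + (Y - c0[2])^2 <= r^2  # z-parallel rod

  masks <- list(BODY = body)
  if (scenario == "lateral") {
    off <- max(3.5, ptv_radius + 2) # centroid stays >= 3 cm off-axis

    if (off + ptv_radius >= body_radius)
      stop("make_planning_case: PTV outside BODY; enlarge body_radius")
    masks$PTV <- sphere(c(off, 0, 0), ptv_radius)
    masks$contralateral <- sphere(c(-off, 0, 0), ptv_radius) & body
  } else if (scenario == "central") {
    if (ptv_radius >= body_radius)
      stop("make_planning_case: PTV outside BODY; enlarge body_radius")
    r_rod <- min(1, ptv_radius / 1.5)
    masks$PTV <- sphere(c(0, 0, 0), ptv_radius)
    # rods abut the PTV surface anteriorly (+y) and posteriorly (-y)
    masks$anterior_rod <- rod(c(0, ptv_radius + r_rod, 0), r_rod) &
      body & !masks$PTV
    masks$posterior_rod <- rod(c(0, -(ptv_radius + r_rod), 0), r_rod) &
      body & !masks$PTV
  } else { # bilateral
    off <- max(3.5, ptv_radius + 2)
    if (off + ptv_radius >= body_radius)
      stop("make_planning_case: PTV outside BODY; enlarge body_radius")
    masks$PTV <- sphere(c(off, 0, 0), ptv_radius)
    r_rod <- min(1, ptv_radius / 1.5)
    masks$ipsilateral_rod <- rod(c(body_radius - 1.5, 0, 0), r_rod) &
      body & !masks$PTV
    masks$contralateral_rod <- rod(c(-(body_radius - 1.5), 0, 0), r_rod) & body
  }
  if (any(masks$PTV & !body))
    stop("make_planning_case: PTV outside BODY")
  list(phantom = p, structures = structure_set(g, masks))
}
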