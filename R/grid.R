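#' Voxel grid geometry
#'
#' A `voxel_grid` describes a regular 3D lattice of voxels in world
#' coordinates. The package convention is: world units are centimetres,
#' right-handed axes with the origin at the machine isocenter, x = lateral,
#' y = anterior (+) to posterior, z = longitudinal. A voxel's world position
#' is its *center*; `origin` is the center of voxel (1, 1, 1) (R arrays are
#' 1-based).
#'
#' @param origin numeric length-3, world position (cm) of the center of the
#'   first voxel.
#' @param spacing numeric length-3, per-axis voxel size (cm); must be > 0.
#' @param dims integer length-3, per-axis voxel counts; must be >= 1.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(dims) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel_grid: spacing must be positive on every axis")
  if (any(is.na(dims)) || any(dims < 1L))
    stop("voxel_grid: dims must be >= 1 on every axis")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) cm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (first voxel center): (%.4g, %.4g, %.4g) cm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Number of voxels in a grid
#' @param grid a [voxel_grid()].
#' @return integer voxel count.
#' @export
grid_nvox <- function(grid) prod(grid$dims)

#' Volume of one voxel (cm^3)
#' @param grid a [voxel_grid()].
#' @export
grid_voxel_volume <- function(grid) prod(grid$spacing)

#' Map world coordinates to (fractional or nearest) voxel indices
#'
#' The affine map is `index = (world - origin) / spacing + 1`; it is
#' invertible by construction. With `nearest = TRUE` indices are rounded to
#' the containing voxel (half-open tie going to the nearer center via
#' `round`).
#'
#' @param grid a [voxel_grid()].
#' @param pts n x 3 matrix (or length-3 vector) of world positions (cm).
#' @param nearest round to integer indices?
#' @return n x 3 matrix of indices (1-based).
#' @export
grid_world_to_index <- function(grid, pts, nearest = TRUE) {
  pts <- rbind_pts(pts)
  idx <- sweep(sweep(pts, 2L, grid$origin, "-"), 2L, grid$spacing, "/") + 1
  if (nearest) idx <- round(idx)
  idx
}

#' Map voxel indices (1-based) to world coordinates of voxel centers
#' @param grid a [voxel_grid()].
#' @param idx n x 3 matrix (or length-3 vector) of indices.
#' @return n x 3 matrix of world positions (cm).
#' @export
grid_index_to_world <- function(grid, idx) {
  idx <- rbind_pts(idx)
  sweep(sweep(idx - 1, 2L, grid$spacing, "*"), 2L, grid$origin, "+")
}

#' Are (integer) indices inside the grid?
#' @param grid a [voxel_grid()].
#' @param idx n x 3 matrix of 1-based indices.
#' @return logical vector of length n.
#' @export
grid_index_inside <- function(grid, idx) {
  idx <- rbind_pts(idx)
  idx[, 1] >= 1 & idx[, 1] <= grid$dims[1] &
    idx[, 2] >= 1 & idx[, 2] <= grid$dims[2] &
    idx[, 3] >= 1 & idx[, 3] <= grid$dims[3]
}

#' World coordinates of voxel centers along one axis
#' @param grid a [voxel_grid()].
#' @param axis 1, 2 or 3.
#' @export
grid_axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing[axis]
}

same_grid <- function(a, b, tol = 1e-9) {
  all(a$dims == b$dims) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

rbind_pts <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  stopifnot(ncol(pts) == 3L)
  pts
}
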