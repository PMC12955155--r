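#' 3D diamond-pattern spot lattice covering PTV + margin
#'
#' Generates a hexagonal-close-packed candidate lattice with
#' nearest-neighbor distance `k` (in-layer hexagonal rows with row pitch
#' `k*sqrt(3)/2` and alternate-row offset `k/2`; layer pitch
#' `k*sqrt(2/3)` with ABAB lateral offset), anchored at the PTV centroid,
#' and retains candidates whose position lies inside
#' `expand_mask(PTV, m)`. The lattice is defined once in world
#' coordinates and shared by all beam directions.
#'
#' @param ptv_mask logical 3D PTV mask.
#' @param grid the [voxel_grid()] the mask lives on.
#' @param m margin (cm), >= 0.
#' @param k spacing factor: lattice nearest-neighbor distance (cm), > 0.
#' @param anchor optional length-3 anchor point (cm); default PTV centroid.
#' @return An object of class `spot_lattice`: list with `k`, `m`,
#'   `anchor`, `positions` (n x 3 world cm, deterministic order), `grid`.
#' @export
generate_diamond_grid <- function(ptv_mask, grid, m, k, anchor = NULL) {
  if (!any(ptv_mask)) stop("generate_diamond_grid: empty PTV")
  if (k <= 0) stop("generate_diamond_grid: spacing factor k must be > 0")
  if (m < 0) stop("generate_diamond_grid: margin m must be >= 0")

  idx <- which(ptv_mask, arr.ind = TRUE)
  centers <- grid_index_to_world(grid, idx)
  if (is.null(anchor)) anchor <- colMeans(centers)

  expanded <- expand_mask(ptv_mask, m, grid$spacing)
  eidx <- which(expanded, arr.ind = TRUE)
  ecenters <- grid_index_to_world(grid, eidx)
  lo <- apply(ecenters, 2, min) - k
  hi <- apply(ecenters, 2, max) + k

  dy <- k * sqrt(3) / 2    # row pitch within a layer
  dz <- k * sqrt(2 / 3)    # layer pitch (ABAB stacking)
  irange <- seq(floor((lo[1] - anchor[1]) / k) - 1,
                ceiling((hi[1] - anchor[1]) / k) + 1)
  jrange <- seq(floor((lo[2] - anchor[2]) / dy) - 1,
                ceiling((hi[2] - anchor[2]) / dy) + 1)
  lrange <- seq(floor((lo[3] - anchor[3]) / dz) - 1,
                ceiling((hi[3] - anchor[3]) / dz) + 1)

  cand <- expand.grid(i = irange, j = jrange, l = lrange,
                      KEEP.OUT.ATTRS = FALSE)
  pj <- cand$j %% 2 # alternate-row offset
  pl <- cand$l %% 2 # ABAB layer offset
  pos <- cbind(
    anchor[1] + cand$i * k + pj * (k / 2) + pl * (k / 2),
    anchor[2] + cand$j * dy + pl * (k * sqrt(3) / 6),
    anchor[3] + cand$l * dz
  )

  vi <- grid_world_to_index(grid, pos)
  inside <- grid_index_inside(grid, vi)
  keep <- logical(nrow(pos))
  if (any(inside)) {
    lin <- vi[inside, 1] +
      grid$dims[1] * (vi[inside, 2] - 1) +
      grid$dims[1] * grid$dims[2] * (vi[inside, 3] - 1)
    keep[inside] <- expanded[lin]
  }
  pos <- pos[keep, , drop = FALSE]
  # deterministic ordering: layer, then row, then column
  ord <- order(cand$l[keep], cand$j[keep], cand$i[keep])
  pos <- pos[ord, , drop = FALSE]
  colnames(pos) <- c("x", "y", "z")

  structure(list(k = k, m = m, anchor = as.numeric(anchor),
                 positions = pos, grid = grid),
            class = "spot_lattice")
}

#' @export
print.spot_lattice <- function(x, ...) {
  cat(sprintf("spot_lattice: %d spots, k = %.3g cm, m = %.3g cm\n",
              nrow(x$positions), x$k, x$m))
  invisible(x)
}

#' Expand a spot lattice into the beamlet catalog
#'
#' One beamlet per (beam, spot) pair, beam-major then lattice order, with
#' per-spot focal lengths computed from each beam's geometry.
#'
#' @param lattice a `spot_lattice`.
#' @param beams list of [beam_config()] objects (>= 1).
#' @param focal_fwhm geometric fluence FWHM at the focus (cm), default 1.
#' @return An object of class `beamlet_catalog`: a data.frame with one
#'   row per beamlet (beam_index, gantry_angle, spot_index, spot_x/y/z,
#'   focal_length, ...) and attribute `beams`.
#' @export
build_catalog <- function(lattice, beams, focal_fwhm = 1) {
  stopifnot(inherits(lattice, "spot_lattice"), length(beams) >= 1)
  if (nrow(lattice$positions) < 1) stop("build_catalog: no spots")
  rows <- lapply(seq_along(beams), function(bi) {
    bc <- beams[[bi]]
    stopifnot(inherits(bc, "beam_config"))
    f <- apply(lattice$positions, 1, function(sp)
      focal_length_for_spot(bc, sp))
    data.frame(beam_index = bi, gantry_angle = bc$gantry_angle,
               lens_radius = bc$lens_radius, lens_to_iso = bc$lens_to_iso,
               energy = bc$energy,
               spot_index = seq_len(nrow(lattice$positions)),
               spot_x = lattice$positions[, 1],
               spot_y = lattice$positions[, 2],
               spot_z = lattice$positions[, 3],
               focal_length = f, focal_fwhm = focal_fwhm)
  })
  cat <- do.call(rbind, rows)
  rownames(cat) <- NULL
  structure(cat, beams = beams, class = c("beamlet_catalog", "data.frame"))
}

#' Reconstruct one beamlet from a catalog row
#' @param catalog a `beamlet_catalog`.
#' @param i row index.
#' @return a [beamlet_spec()].
#' @export
catalog_beamlet <- function(catalog, i) {
  r <- catalog[i, ]
  bc <- beam_config(r$gantry_angle, r$lens_radius, r$lens_to_iso, r$energy)
  beamlet_spec(bc, c(r$spot_x, r$spot_y, r$spot_z), r$focal_fwhm)
}
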