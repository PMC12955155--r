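#' Compute the sparse dose-influence matrix
#'
#' Simulates every beamlet of the catalog into the phantom and assembles
#' the voxels x beamlets operator A (Gy per history per unit beamlet
#' weight): `dose(w) = A w`. Per-beamlet columns are pruned at
#' `tau * max(column)` before storage. Each beamlet gets a deterministic
#' sub-seed derived from the global seed and its (beam, spot) index, so
#' the aggregate matrix is independent of any scheduling order.
#'
#' @param phantom a [phantom()].
#' @param catalog a `beamlet_catalog` from [build_catalog()].
#' @param cfg a [transport_config()]; `cfg$seed` is the global seed.
#' @param tau pruning threshold in [0, 1), default 1e-3.
#' @param verbose print per-beamlet progress every 25 beamlets.
#' @return An object of class `dose_influence_matrix`: list with `A`
#'   (dgCMatrix, nvox x nbeamlets), `grid`, `catalog`, `tau`,
#'   `n_histories`.
#' @export
compute_influence_matrix <- function(phantom, catalog, cfg = transport_config(),
                                     tau = 1e-3, verbose = FALSE) {
  stopifnot(inherits(phantom, "phantom"),
            inherits(catalog, "beamlet_catalog"))
  if (tau < 0 || tau >= 1)
    stop("compute_influence_matrix: tau must be in [0, 1)")
  nb <- nrow(catalog)
  nv <- grid_nvox(phantom$grid)
  base_seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)

  ii <- vector("list", nb)
  xx <- vector("list", nb)
  for (b in seq_len(nb)) {
    sub <- beamlet_subseed(base_seed, catalog$beam_index[b],
                           catalog$spot_index[b])
    bl <- catalog_beamlet(catalog, b)
    rays <- sample_phase_space(bl, cfg$n_histories, seed = sub)
    dg <- transport(phantom, rays, cfg)
    d <- as.numeric(dg$dose)
    thr <- tau * max(d)
    keep <- which(d > 0 & d >= thr)
    ii[[b]] <- keep
    xx[[b]] <- d[keep]
    if (verbose && b %% 25L == 0L)
      message(sprintf("  beamlet %d / %d", b, nb))
  }
  A <- Matrix::sparseMatrix(
    i = unlist(ii),
    j = rep.int(seq_len(nb), lengths(ii)),
    x = unlist(xx), dims = c(nv, nb)
  )
  structure(list(A = A, grid = phantom$grid, catalog = catalog, tau = tau,
                 n_histories = cfg$n_histories, seed = base_seed),
            class = "dose_influence_matrix")
}

# deterministic per-beamlet sub-seed (< 2^31) from the global seed
beamlet_subseed <- function(seed, beam_index, spot_index) {
  m <- 2147483647
  h <- (as.double(seed) %% m)
  h <- (h * 48271 + as.double(beam_index) * 104729) %% m
  h <- (h * 48271 + as.double(spot_index) * 7919) %% m
  as.integer(h)
}

#' Dose distribution for beamlet weights
#'
#' @param dim a `dose_influence_matrix`.
#' @param w nonnegative weight vector, one entry per beamlet.
#' @return 3D dose array (Gy) on the matrix grid.
#' @export
dose_from_weights <- function(dim, w) {
  stopifnot(inherits(dim, "dose_influence_matrix"),
            length(w) == ncol(dim$A))
  array(as.numeric(dim$A %*% w), dim = dim$grid$dims)
}

#' Write / read a dose-influence matrix container
#'
#' Plain-text container: a JSON header (grid, tau, seed, beamlet catalog)
#' followed by the CSC triplets printed with 17 significant digits, so
#' doubles round-trip bit-exactly.
#'
#' @param dim a `dose_influence_matrix`.
#' @param path file path.
#' @return `write_influence_matrix` returns `path` invisibly;
#'   `read_influence_matrix` returns the reconstructed object.
#' @export
write_influence_matrix <- function(dim, path) {
  ts <- Matrix::mat2triplet(dim$A)
  hdr <- jsonlite::toJSON(list(
    format = "fvheeplan-influence-v1",
    nrow = nrow(dim$A), ncol = ncol(dim$A), nnz = length(ts$x),
    tau = dim$tau, n_histories = dim$n_histories, seed = dim$seed,
    grid = list(origin = dim$grid$origin, spacing = dim$grid$spacing,
                dims = dim$grid$dims),
    catalog = as.data.frame(dim$catalog)
  ), auto_unbox = TRUE, digits = I(17))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  writeLines(sprintf("%d %d %.17g", ts$i, ts$j, ts$x), con)
  invisible(path)
}

#' @rdname write_influence_matrix
#' @export
read_influence_matrix <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- jsonlite::fromJSON(readLines(con, n = 1L))
  if (!identical(hdr$format, "fvheeplan-influence-v1"))
    stop("read_influence_matrix: unrecognized container format")
  dat <- utils::read.table(con, col.names = c("i", "j", "x"),
                           colClasses = c("integer", "integer", "numeric"))
  g <- voxel_grid(hdr$grid$origin, hdr$grid$spacing, hdr$grid$dims)
  A <- Matrix::sparseMatrix(i = dat$i, j = dat$j, x = dat$x,
                            dims = c(hdr$nrow, hdr$ncol))
  cat <- hdr$catalog
  beams <- lapply(unique(cat$beam_index), function(bi) {
    r <- cat[cat$beam_index == bi, ][1, ]
    beam_config(r$gantry_angle, r$lens_radius, r$lens_to_iso, r$energy)
  })
  catalog <- structure(cat, beams = beams,
                       class = c("beamlet_catalog", "data.frame"))
  structure(list(A = A, grid = g, catalog = catalog, tau = hdr$tau,
                 n_histories = hdr$n_histories, seed = hdr$seed),
            class = "dose_influence_matrix")
}
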