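# Shared fixtures and independent brute-force oracles. Oracles are coded
# from the definitions, separately from the package implementations.

# small water box with the upstream face at y = 0 (beam enters from +y)
fix_water_box <- function(side = c(10, 12, 10), voxel = 0.5) {
  make_water_box(side, voxel, center = c(0, -side[2] / 2, 0))
}

# beamlet in the water-tank characterization geometry: lens `gap` cm
# before the surface, focus at depth `f - gap`
fix_beamlet <- function(f = 15, gap = 7, energy = 250, fwhm = 1) {
  beam <- beam_config(0, lens_radius = 5, lens_to_iso = gap, energy = energy)
  beamlet_spec(beam, c(0, gap - f, 0), focal_fwhm = fwhm)
}

# random blob mask: union of a few random balls (deterministic per seed)
fix_blob_mask <- function(dims = c(24, 24, 24), spacing = 0.25, seed = 1,
                          n_balls = 3) {
  set.seed(seed)
  m <- array(FALSE, dims)
  ctr <- (dims + 1) / 2
  for (b in seq_len(n_balls)) {
    c0 <- ctr + runif(3, -dims / 6, dims / 6)
    r <- runif(1, 2, 4) # in voxels
    for (k in seq_len(dims[3])) {
      dz2 <- (k - c0[3])^2
      if (dz2 > r^2) next
      for (j in seq_len(dims[2])) {
        dyz2 <- (j - c0[2])^2 + dz2
        if (dyz2 > r^2) next
        i <- which((seq_len(dims[1]) - c0[1])^2 + dyz2 <= r^2)
        m[i, j, k] <- TRUE
      }
    }
  }
  m
}

# brute-force all-pairs mask expansion: voxel center within m of any
# mask voxel center
oracle_expand_mask <- function(mask, m, spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  idx <- which(mask, arr.ind = TRUE)
  src <- t(t(idx) * spacing)
  out <- array(FALSE, dim(mask))
  all_idx <- which(!is.na(mask), arr.ind = TRUE)
  pts <- t(t(all_idx) * spacing)
  for (r in seq_len(nrow(pts))) {
    d2 <- min(colSums((t(src) - pts[r, ])^2))
    out[all_idx[r, 1], all_idx[r, 2], all_idx[r, 3]] <- d2 <= m^2 + 1e-12
  }
  out
}

# independent HCP lattice enumerator: loops over integer triples, builds
# positions from the layer/row formulas, retains spots whose containing
# voxel lies in the expanded mask
oracle_hcp_spots <- function(mask, grid, m, k, anchor) {
  expanded <- expand_mask(mask, m, grid$spacing)
  dy <- k * sqrt(3) / 2
  dz <- k * sqrt(2 / 3)
  ext <- apply(grid_index_to_world(grid, which(expanded, arr.ind = TRUE)),
               2, range)
  kept <- 0L
  for (l in seq(floor((ext[1, 3] - anchor[3] - k) / dz),
                ceiling((ext[2, 3] - anchor[3] + k) / dz))) {
    pl <- l %% 2
    z <- anchor[3] + l * dz
    for (j in seq(floor((ext[1, 2] - anchor[2] - k) / dy),
                  ceiling((ext[2, 2] - anchor[2] + k) / dy))) {
      y <- anchor[2] + j * dy + pl * k * sqrt(3) / 6
      off <- (j %% 2) * k / 2 + pl * k / 2
      for (i in seq(floor((ext[1, 1] - anchor[1] - k) / k),
                    ceiling((ext[2, 1] - anchor[1] + k) / k))) {
        x <- anchor[1] + i * k + off
        vi <- round((c(x, y, z) - grid$origin) / grid$spacing) + 1
        if (any(vi < 1) || any(vi > grid$dims)) next
        if (expanded[vi[1], vi[2], vi[3]]) kept <- kept + 1L
      }
    }
  }
  kept
}

# exhaustive grid-search minimizer for <=3-beamlet objective problems
oracle_grid_search <- function(A, objectives, structures, lo = 0, hi = 5,
                               step = 0.05, refine = 0.01) {
  A <- as.matrix(A)
  eval_many <- function(W) { # W: nb x m combinations
    D <- A %*% W
    vals <- numeric(ncol(W))
    for (o in objectives) {
      vox <- which(structures$masks[[o$structure]])
      dv <- D[vox, , drop = FALSE]
      cw <- o$weight / length(vox)
      e2 <- switch(o$type,
        uniform = (dv - o$d_ref)^2,
        max_dose = pmax(dv - o$d_ref, 0)^2, # pmax(m, 0) keeps dim
        min_dose = pmax(o$d_ref - dv, 0)^2,
        stop("oracle supports uniform/max/min only"))
      vals <- vals + cw * colSums(e2)
    }
    vals
  }
  search <- function(grids) {
    best <- Inf; best_w <- NULL
    combos <- as.matrix(expand.grid(grids))
    for (s in split(seq_len(nrow(combos)),
                    ceiling(seq_len(nrow(combos)) / 20000))) {
      v <- eval_many(t(combos[s, , drop = FALSE]))
      i <- which.min(v)
      if (v[i] < best) { best <- v[i]; best_w <- combos[s[i], ] }
    }
    list(value = best, w = best_w)
  }
  g1 <- search(rep(list(seq(lo, hi, by = step)), ncol(A)))
  g2 <- search(lapply(g1$w, function(wi)
    seq(max(lo, wi - step), min(hi, wi + step), by = refine)))
  if (g2$value < g1$value) g2 else g1
}

# brute-force DVH quantities by direct counting on the voxel values
oracle_vd <- function(doses, d) 100 * sum(doses >= d) / length(doses)
oracle_dx <- function(doses, x) {
  ds <- sort(doses, decreasing = TRUE)
  n <- length(ds)
  q <- x / 100
  if (q <= 1 / n) return(ds[1])
  approx(seq_len(n) / n, ds, xout = q)$y
}
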