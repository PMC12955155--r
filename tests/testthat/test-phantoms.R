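test_that("water-box construction, voxelization and mass", {
  p <- make_water_box(c(20, 20, 30), 0.25)
  expect_identical(p$grid$dims, c(80L, 80L, 120L))
  expect_true(all(p$density == 1.0))
  expect_equal(phantom_mass(p), 12000) # 20*20*30 cm^3 at 1 g/cm^3

  cube <- make_water_box(c(1, 1, 1), 1)
  expect_identical(cube$grid$dims, c(1L, 1L, 1L))
  expect_equal(phantom_mass(cube), 1)

  expect_error(make_water_box(c(-1, 2, 2), 0.5), "positive")
  expect_error(make_water_box(c(1, 1, 1), 0), "positive")
})

test_that("grid world<->index mapping is affine and invertible", {
  g <- voxel_grid(c(-3, 1, 0.5), c(0.25, 0.5, 1), c(10, 8, 6))
  idx <- cbind(c(1, 10, 4), c(1, 8, 5), c(1, 6, 2))
  w <- grid_index_to_world(g, idx)
  back <- grid_world_to_index(g, w)
  expect_equal(back, idx, ignore_attr = TRUE)
  # off-center points land in the containing voxel
  expect_equal(grid_world_to_index(g, w + 0.1 * rep(g$spacing,
                                                    each = 3)), idx,
               ignore_attr = TRUE)
  expect_error(voxel_grid(c(0, 0, 0), c(0, 1, 1), c(2, 2, 2)), "positive")
})

test_that("expand_mask: identity at m = 0 and ball growth from one voxel", {
  m <- fix_blob_mask(seed = 3)
  expect_identical(expand_mask(m, 0, 0.25), m)
  expect_error(expand_mask(m, -0.1, 0.25), "m must be")

  single <- array(FALSE, c(11, 11, 11))
  single[6, 6, 6] <- TRUE
  e <- expand_mask(single, 0.5, 0.25) # ball of radius 2 voxels
  expect_identical(e, oracle_expand_mask(single, 0.5, 0.25))
  # |{v : ||v|| <= 2}| in voxel units: 1+6+12+8+6 = 33
  expect_identical(sum(e), 33L)
})

test_that("expand_mask matches brute force and is monotone in m", {
  spacing <- c(0.2, 0.25, 0.3) # deliberately anisotropic
  m <- fix_blob_mask(dims = c(20, 22, 18), seed = 11)
  prev <- m
  for (mar in c(0.15, 0.3, 0.6)) {
    e <- expand_mask(m, mar, spacing)
    expect_identical(e, oracle_expand_mask(m, mar, spacing),
                     label = sprintf("margin %.2f", mar))
    expect_true(all(e[prev])) # superset of the previous margin
    prev <- e
  }
})

test_that("case-B-style margin: sphere r=1 expanded by 0.5 is sphere r=1.5", {
  dims <- c(24, 24, 24); spacing <- 0.25
  ctr <- (dims + 1) / 2
  ax <- (seq_len(dims[1]) - ctr[1]) * spacing
  R2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  sphere1 <- array(R2 <= 1^2, dims)
  e <- expand_mask(sphere1, 0.5, spacing)
  expect_identical(e, oracle_expand_mask(sphere1, 0.5, spacing))
})

test_that("synthetic planning scenarios satisfy their geometric contracts", {
  tpl <- case_templates("F")
  lat <- make_planning_case(tpl, "lateral", voxel_size = 0.4)
  ptv <- lat$structures$masks$PTV
  centroid <- colMeans(grid_index_to_world(lat$phantom$grid,
                                           which(ptv, arr.ind = TRUE)))
  expect_gte(abs(centroid[1]), 3) # PTV well off-axis
  expect_false(any(ptv & lat$structures$masks$contralateral))
  expect_true(all(!ptv | lat$structures$masks$BODY)) # PTV inside BODY

  cen <- make_planning_case(case_templates("P1"), "central",
                            voxel_size = 0.4)
  cc <- colMeans(grid_index_to_world(cen$phantom$grid,
                                     which(cen$structures$masks$PTV,
                                           arr.ind = TRUE)))
  expect_lt(sqrt(cc[1]^2 + cc[2]^2), 0.5) # on axis
  # posterior rod abuts the PTV: nearest surface gap below one voxel
  rod <- which(cen$structures$masks$posterior_rod, arr.ind = TRUE)
  pw <- grid_index_to_world(cen$phantom$grid,
                            which(cen$structures$masks$PTV, arr.ind = TRUE))
  rw <- grid_index_to_world(cen$phantom$grid, rod)
  gap <- min(apply(rw, 1, function(r) min(sqrt(colSums((t(pw) - r)^2)))))
  expect_lt(gap, 2 * 0.4)
  expect_true(all(rw[, 2] < 0)) # posterior side

  # voxelized PTV volume within one voxel shell of the analytic sphere
  r <- 1.5
  v_analytic <- 4 / 3 * pi * r^3
  v_vox <- sum(ptv) * grid_voxel_volume(lat$phantom$grid)
  shell <- 4 * pi * r^2 * 0.4 * sqrt(3)
  expect_lt(abs(v_vox - v_analytic), shell)
})

test_that("NRRD volumes round-trip grids, densities and masks", {
  p <- make_water_box(c(4, 5, 6), 0.5, center = c(1, -2, 0.25))
  p$density[2, 3, 4] <- 0.3 # float32-representable? not exactly -> cast
  f <- tempfile(fileext = ".nrrd")
  write_volume(p, f)
  q <- read_volume(f)
  expect_s3_class(q, "phantom")
  expect_equal(q$grid$origin, p$grid$origin)
  expect_equal(q$grid$spacing, p$grid$spacing)
  expect_identical(q$grid$dims, p$grid$dims)
  # payload round-trips the float32 cast bit-exactly: write again, compare
  f2 <- tempfile(fileext = ".nrrd")
  write_volume(q, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))

  m <- fix_blob_mask(seed = 5)
  g <- voxel_grid(c(0, 0, 0), c(0.25, 0.25, 0.25), dim(m))
  fm <- tempfile(fileext = ".nrrd")
  write_volume(m, fm, grid = g)
  m2 <- read_volume(fm)
  expect_identical(sum(m2), sum(m))
  expect_identical(array(m2, dim(m)), m)

  expect_error(read_volume(tempfile(fileext = ".nii")), "NIfTI")
  # 2D payloads are rejected
  f2d <- tempfile(fileext = ".nrrd")
  writeLines(c("NRRD0004", "type: float", "dimension: 2", "sizes: 4 4",
               "encoding: raw", ""), f2d)
  expect_error(read_volume(f2d), "3D")
})

test_that("case templates carry the published planning parameters", {
  tpl <- case_templates()
  expect_named(tpl, c("B", "H", "L1", "L2", "P1", "P2", "F"))
  for (nm in c("B", "H", "L1", "L2"))
    expect_equal(tpl[[nm]]$spacing_factor, 0.36)
  for (nm in c("P1", "P2", "F"))
    expect_equal(tpl[[nm]]$spacing_factor, 0.46)
  expect_equal(tpl$B$d_pres, 12)
  expect_equal(tpl$B$normalization, "D95")
  expect_equal(tpl$B$beam_angles, c(-130, -90, 130))
  expect_equal(tpl$L1$normalization, "D50")
  expect_equal(tpl$F$d_pres, 46.5)
  expect_equal(tpl$F$margin, 0.25)
  expect_equal(tpl$F$n_fractions, 10)
  expect_true(all(vapply(tpl, function(t) t$energy, numeric(1)) == 250))
  # JSON sidecar round trip
  f <- tempfile(fileext = ".json")
  write_case_template(tpl$F, f)
  back <- read_case_template(f)
  expect_equal(unclass(back), unclass(tpl$F))
})

test_that("structure_set enforces the planning invariants", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(4, 4, 4))
  body <- array(TRUE, c(4, 4, 4))
  ptv <- array(FALSE, c(4, 4, 4)); ptv[2, 2, 2] <- TRUE
  expect_silent(structure_set(g, list(PTV = ptv, BODY = body)))
  expect_error(structure_set(g, list(PTV = ptv)), "required")
  expect_error(structure_set(g, list(PTV = array(FALSE, c(4, 4, 4)),
                                     BODY = body)), "empty")
  outside <- ptv; outside[1, 1, 1] <- TRUE
  body2 <- body; body2[1, 1, 1] <- FALSE
  expect_error(structure_set(g, list(PTV = outside, BODY = body2)),
               "contained")
})
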