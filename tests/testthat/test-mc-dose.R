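test_that("vacuum phantom: zero dose, full energy escapes on straight rays", {
  g <- voxel_grid(c(-2, -2, -2), c(0.5, 0.5, 0.5), c(9, 9, 9))
  vac <- phantom(g, array(0, c(9, 9, 9)))
  bl <- fix_beamlet(f = 9)
  cfg <- transport_config(n_histories = 500, seed = 2)
  dg <- simulate_beamlet(vac, bl, cfg)
  expect_true(all(dg$dose == 0))
  expect_equal(dg$ledger[["escaped"]], dg$ledger[["input"]])
  expect_equal(dg$ledger[["collisional"]] + dg$ledger[["radiative"]], 0)
})

test_that("energy bookkeeping closes and dose is bounded by input energy", {
  box <- fix_water_box()
  bl <- fix_beamlet(f = 12)
  cfg <- transport_config(n_histories = 5e3, seed = 4)
  dg <- simulate_beamlet(box, bl, cfg)
  expect_lt(abs(energy_balance(dg)), 1e-6)
  # sum(dose * mass) = collisional + sub-cutoff deposits <= n * E0
  edep <- sum(dg$dose * box$density) * grid_voxel_volume(box$grid) /
    1.602176634e-10 * dg$n_histories
  expect_equal(edep,
               dg$ledger[["collisional"]] + dg$ledger[["sub_cutoff"]],
               tolerance = 1e-9)
  expect_lt(edep, dg$n_histories * 250)
  expect_error(transport(box, structure(list(pos = matrix(0, 0, 3)),
                                        class = "ray_set"), cfg),
               "empty RaySet")
})

test_that("batch uncertainty follows 1/sqrt(N) statistics", {
  box <- fix_water_box()
  bl <- fix_beamlet(f = 12)
  unc <- vapply(c(1e3, 4e3, 1e4, 1e5), function(n) {
    dg <- simulate_beamlet(box, bl, transport_config(n_histories = n,
                                                     seed = 11))
    mean_high_dose_uncertainty(dg)
  }, numeric(1))
  # quadrupling N halves the mean relative uncertainty; the full
  # 3-decade slope fit is in the acceptance suite
  expect_equal(unc[1] / unc[2], 2, tolerance = 0.15)
  expect_true(all(diff(unc) < 0))
})

test_that("lateral profiles through the axis are mirror-symmetric", {
  box <- fix_water_box(side = c(10, 12, 10), voxel = 0.25)
  bl <- fix_beamlet(f = 12)
  ch <- characterize(bl, box, transport_config(n_histories = 3e4, seed = 13))
  prof <- ch$profiles[ch$profiles$depth_label == "dmax+0 cm", ]
  d <- prof$dose[order(prof$offset_cm)]
  x <- sort(prof$offset_cm)
  core <- abs(x) < 2
  asym <- abs(d[core] - rev(d[core])) /
    pmax(d[core] + rev(d[core]), max(d) * 1e-3)
  expect_lt(median(asym), 0.15) # MC noise level at these statistics
})

test_that("influence matrix: pruning, linearity, bit-exact persistence", {
  box <- fix_water_box(side = c(8, 10, 8), voxel = 0.5)
  lat <- structure(list(k = 1, m = 0, anchor = c(0, -5, 0),
                        positions = rbind(c(0, -5, 0), c(1, -5, 0)),
                        grid = box$grid), class = "spot_lattice")
  beams <- list(beam_config(0, lens_to_iso = 7))
  catalog <- build_catalog(lat, beams)
  cfg <- transport_config(n_histories = 2e3, seed = 5)

  # tau = 0: dense column equals the standalone transport of the same
  # sub-seeded beamlet, exactly
  infl0 <- compute_influence_matrix(box, catalog, cfg, tau = 0)
  sub <- fvheeplan:::beamlet_subseed(5L, 1L, 1L)
  bl1 <- catalog_beamlet(catalog, 1)
  rays <- sample_phase_space(bl1, 2e3, seed = sub)
  dg1 <- transport(box, rays, cfg)
  expect_identical(as.numeric(infl0$A[, 1]), as.numeric(dg1$dose))

  # tau = 1e-3 retains >= 99% of the column sum
  infl <- compute_influence_matrix(box, catalog, cfg, tau = 1e-3)
  expect_gte(sum(infl$A[, 1]), 0.99 * sum(infl0$A[, 1]))
  expect_true(all(infl$A@x > 0))

  # linearity: A w equals the weighted sum of the columns exactly
  w <- c(0.7, 2.5)
  d_lin <- dose_from_weights(infl, w)
  d_sum <- 0.7 * array(infl$A[, 1], box$grid$dims) +
    2.5 * array(infl$A[, 2], box$grid$dims)
  expect_equal(d_lin, d_sum, tolerance = 1e-14)

  # persisted container round-trips bit-exactly
  f <- tempfile(fileext = ".txt")
  write_influence_matrix(infl, f)
  back <- read_influence_matrix(f)
  expect_identical(back$A@x, infl$A@x)
  expect_identical(back$A@i, infl$A@i)
  expect_equal(back$grid$origin, infl$grid$origin)
  expect_equal(back$tau, infl$tau)
  expect_equal(back$catalog$focal_length, infl$catalog$focal_length)

  expect_error(compute_influence_matrix(box, catalog, cfg, tau = 1.2),
               "tau")
  expect_error(dose_from_weights(infl, c(1, 2, 3)))
})

test_that("Fermi-Eyges limits: vacuum envelope and constant-T closed form", {
  depths <- c(1, 3, 5, 8)
  fe0 <- fermi_eyges_sigma(depths, 250, focal_length = 20,
                           lens_to_surface = 7, scattering_power = 0)
  sig_w <- 1 / sqrt(8 * log(2))
  l <- 7 + depths
  expect_equal(fe0$sigma,
               sqrt(25 / 4 * (1 - l / 20)^2 + sig_w^2 * (l / 20)^2),
               tolerance = 1e-12)
  # A2 with constant scattering power: T z^3 / 3
  Tc <- 4e-4
  expect_equal(fermi_eyges_a2(depths, Tc, step = 1e-3),
               Tc * depths^3 / 3, tolerance = 1e-4)
})

test_that("Fermi-Eyges sigma matches MC within 10% down to 10 cm", {
  box <- make_water_box(c(12, 14, 12), 0.25, center = c(0, -7, 0))
  bl <- fix_beamlet(f = 20)
  dg <- simulate_beamlet(box, bl, transport_config(n_histories = 4e4,
                                                   seed = 3))
  depths <- c(2, 4, 6, 8, 10)
  mc <- mc_lateral_sigma(dg, depths)
  fe <- fermi_eyges_sigma(depths, 250, focal_length = 20,
                          lens_to_surface = 7)
  expect_true(all(abs(mc$sigma / fe$sigma - 1) < 0.10))
})

test_that("characterization: dmax tracks focal length; energy narrows dmax", {
  box <- fix_water_box(side = c(10, 16, 10), voxel = 0.5)
  cfg <- transport_config(n_histories = 8e3, seed = 17)
  dmax <- vapply(c(10, 15, 20), function(f) {
    characterize(fix_beamlet(f = f), box, cfg)$dmax_depth
  }, numeric(1))
  expect_true(all(diff(dmax) > 0)) # deeper focus -> deeper maximum

  # at fixed geometry the 250 MeV beam is at least as narrow at dmax
  sig_of <- function(E) {
    bl <- fix_beamlet(f = 12, energy = E)
    ch <- characterize(bl, box, cfg)
    mc_lateral_sigma(ch$dose_grid, ch$dmax_depth)$sigma
  }
  expect_lte(sig_of(250), sig_of(50) * 1.05)

  g <- voxel_grid(c(-2, -2, -2), c(0.5, 0.5, 0.5), c(9, 9, 9))
  vac <- phantom(g, array(0, c(9, 9, 9)))
  expect_error(characterize(fix_beamlet(f = 9), vac, cfg), "undefined")
})
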