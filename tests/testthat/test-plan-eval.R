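test_that("cumulative DVH: step function, counting, brute-force probes", {
  uni <- rep(3.2, 50)
  mask <- rep(TRUE, 50)
  dvh <- compute_dvh(uni, mask)
  expect_equal(volume_at_dose(dvh, 3.2), 100)
  expect_equal(volume_at_dose(dvh, 3.21), 0)
  expect_equal(dvh$volume[1], 1 / 50)
  expect_equal(dvh$volume[50], 1)

  d4 <- compute_dvh(c(1, 2, 3, 4), rep(TRUE, 4))
  expect_equal(volume_at_dose(d4, 2.5), 50)

  set.seed(9)
  doses <- rexp(1000, 0.2)
  dvh1k <- compute_dvh(doses, rep(TRUE, 1000))
  for (p in seq(0, max(doses) * 1.02, length.out = 100))
    expect_equal(volume_at_dose(dvh1k, p), oracle_vd(doses, p))

  expect_error(compute_dvh(doses, rep(FALSE, 1000)), "empty mask")
})

test_that("Dx and Vd agree with sorting oracles and stay consistent", {
  doses <- as.numeric(1:100)
  dvh <- compute_dvh(doses, rep(TRUE, 100))
  expect_equal(dose_at_volume(dvh, 50), oracle_dx(doses, 50))
  expect_equal(dose_at_volume(dvh, 50), 51) # hottest 50% all get >= 51
  expect_equal(volume_at_dose(dvh, 50.5), 50)
  expect_equal(dose_at_volume(dvh, 0.5), 100) # above the top voxel
  expect_error(dose_at_volume(dvh, 0), "x must be")
  expect_error(dose_at_volume(dvh, 101), "x must be")

  # uniform dose: Dx = d* for every x
  duni <- compute_dvh(rep(7, 9), rep(TRUE, 9))
  for (x in c(2, 50, 95, 98, 100))
    expect_equal(dose_at_volume(duni, x), 7)

  # consistency V(Dx) >= x up to the interpolation convention (1 voxel)
  set.seed(31)
  rd <- runif(200, 0, 10)
  rdvh <- compute_dvh(rd, rep(TRUE, 200))
  for (x in c(2, 50, 95, 98))
    expect_gte(volume_at_dose(rdvh, dose_at_volume(rdvh, x)),
               x - 100 / 200)
})

test_that("homogeneity index: uniform, arithmetic, undefined", {
  expect_equal(homogeneity_index(compute_dvh(rep(5, 20), rep(TRUE, 20))), 0)
  # D2 = 12, D98 = 10, D50 = 11 -> 2/11
  doses <- c(rep(12, 2), rep(11, 95), rep(10, 3))
  dvh <- compute_dvh(doses, rep(TRUE, 100))
  expect_equal(dose_at_volume(dvh, 2), 12)
  expect_equal(dose_at_volume(dvh, 98), 10)
  expect_equal(homogeneity_index(dvh), 2 / 11)
  expect_warning(hi0 <- homogeneity_index(compute_dvh(rep(0, 10),
                                                      rep(TRUE, 10))),
                 "undefined")
  expect_true(is.nan(hi0))
})

test_that("Paddick CI: closed-form toys and storage-order invariance", {
  dims <- c(10, 10, 10)
  tv <- array(FALSE, dims); tv[3:6, 3:6, 3:6] <- TRUE
  # PIV == TV
  dose <- array(0, dims); dose[tv] <- 10
  expect_equal(paddick_ci(dose, tv, 10), 1)
  # PIV disjoint from TV
  d2 <- array(0, dims); d2[8:9, 8:9, 8:9] <- 10
  expect_equal(paddick_ci(d2, tv, 10), 0)
  # |TV| = 64, |PIV| = 128, overlap = 64 -> 0.5
  d3 <- array(0, dims); d3[3:6, 3:6, 3:10] <- 10
  expect_equal(sum(d3 >= 10), 128)
  expect_equal(paddick_ci(d3, tv, 10), 0.5)
  expect_warning(ci0 <- paddick_ci(array(0, dims), tv, 10), "empty")
  expect_equal(ci0, 0)

  # reversing storage order leaves every metric unchanged
  set.seed(12)
  d4 <- array(runif(1000, 0, 12), dims)
  rev3 <- function(a) a[dims[1]:1, dims[2]:1, dims[3]:1]
  expect_equal(paddick_ci(rev3(d4), rev3(tv), 6), paddick_ci(d4, tv, 6))
  expect_equal(homogeneity_index(compute_dvh(rev3(d4), rev3(tv))),
               homogeneity_index(compute_dvh(d4, tv)))
})

test_that("plan_report: columns, best flags, differences, round trip", {
  dims <- c(8, 8, 8)
  g <- voxel_grid(c(0, 0, 0), rep(0.5, 3), dims)
  ptv <- array(FALSE, dims); ptv[3:6, 3:6, 3:6] <- TRUE
  oar <- array(FALSE, dims); oar[1:2, , ] <- TRUE
  body <- array(TRUE, dims)
  ss <- structure_set(g, list(PTV = ptv, BODY = body, OAR = oar))
  set.seed(2)
  dose <- array(runif(512, 0, 2), dims); dose[ptv] <- dose[ptv] + 9

  one <- plan_report(list(fVHEE = dose), ss, d_pres = 10)
  expect_false(any(grepl("^diff_", names(one))))

  two <- plan_report(list(a = dose, b = dose), ss, d_pres = 10)
  expect_true(all(two$diff_b == 0, na.rm = TRUE))

  # a plan with a colder OAR wins the OAR rows
  dose2 <- dose; dose2[oar] <- dose2[oar] * 0.5
  cmp <- plan_report(list(hot = dose, cold = dose2), ss, d_pres = 10)
  oar_rows <- cmp$structure == "OAR" & cmp$metric %in% c("D2", "Dmean")
  expect_true(all(cmp$best[oar_rows] == "cold"))

  # JSON round trip reproduces the stored metric values bit-exactly
  pre <- tempfile()
  plan_report(list(a = dose, b = dose2), ss, d_pres = 10, out_prefix = pre)
  back <- jsonlite::fromJSON(paste0(pre, ".json"))
  mem <- plan_report(list(a = dose, b = dose2), ss, d_pres = 10)
  expect_identical(back$a, mem$a)
  expect_identical(back$b, mem$b)
  expect_true(file.exists(paste0(pre, ".csv")))
})

test_that("plan_metrics assembles the target and OAR panel", {
  dims <- c(8, 8, 8)
  g <- voxel_grid(c(0, 0, 0), rep(0.5, 3), dims)
  ptv <- array(FALSE, dims); ptv[3:6, 3:6, 3:6] <- TRUE
  ss <- structure_set(g, list(PTV = ptv, BODY = array(TRUE, dims)))
  dose <- array(0.5, dims); dose[ptv] <- 10
  pm <- plan_metrics(dose, ss, d_pres = 10)
  expect_equal(pm$structures$PTV$V95, 100)
  expect_equal(pm$structures$PTV$D50, 10)
  expect_equal(pm$HI, 0)
  expect_equal(pm$CI, 1)
  # D2 >= D50 >= D98 ordering
  with(pm$structures$BODY, expect_true(D2 >= D50 && D50 >= D98))
})
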