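# NEMA IQ metrics: uniformity, recovery coefficients, spill-over ratios.

test_that("voi_statistics on a constant image has zero %SD", {
  img <- manual_image(array(7, c(10, 10, 6)))
  st <- voi_statistics(img, cylindrical_voi(c(0, 0, 0), 6, 4))
  expect_equal(st$mean, 7)
  expect_equal(st$maximum, 7)
  expect_equal(st$minimum, 7)
  expect_equal(st$pct_sd, 0)
})

test_that("voi_statistics uses the sample (n-1) standard deviation", {
  vals <- array(0, c(3, 3, 3))
  vals[2, 2, ] <- c(90, 100, 110)
  img <- manual_image(vals)
  # VOI = the central column only: exactly three voxels
  st <- voi_statistics(img, cylindrical_voi(c(0, 0, 0), 1.2, 3))
  expect_equal(st$n, 3L)
  expect_equal(st$mean, 100)
  expect_equal(st$sd, 10)            # sd({90,100,110}, n-1)
  expect_equal(st$pct_sd, 10)
})

test_that("voi_statistics error paths: empty VOI, zero mean with spread", {
  img <- manual_image(array(1, c(10, 10, 4)))
  expect_error(voi_statistics(img, cylindrical_voi(c(100, 0, 0), 2, 2)),
               "no voxel")
  vals <- array(0, c(3, 3, 3)); vals[2, 2, ] <- c(-1, 0, 1)
  expect_error(voi_statistics(manual_image(vals),
                              cylindrical_voi(c(0, 0, 0), 1.2, 3)),
               "undefined")
})

test_that("recovery coefficient and its uncertainty follow the defining formula", {
  # cold background with one hot rod column at 80 against a uniform-region
  # mean of 100: RC = 0.8, sigma_RC = 100 * sqrt(0 + (5/100)^2) = 5
  vals <- array(0, c(21, 21, 10))
  vals[11, 11, ] <- 80
  img <- manual_image(vals)
  uni <- list(mean = 100, sd = 5)
  rods <- data.frame(diameter = 2, x = 0, y = 0)
  rc <- recovery_coefficients(img, rods, uni, axial_center = 0,
                              axial_window = 4)
  expect_equal(rc$c_rod, 80)
  expect_equal(rc$std_rod, 0)
  expect_equal(rc$rc, 0.8)
  expect_equal(rc$sigma_rc, 5)
})

test_that("the rod search picks the ROI maximum of the averaged image", {
  vals <- array(1, c(31, 31, 10))
  vals[18, 14, ] <- 9       # hot pixel offset from the nominal center
  vals[2, 2, ] <- 50        # hotter pixel far outside the ROI: ignored
  img <- manual_image(vals)
  rc <- recovery_coefficients(img, data.frame(diameter = 4, x = 1, y = -1),
                              list(mean = 1, sd = 0), axial_window = 6)
  expect_equal(rc$c_rod, 9)
})

test_that("noise-free unblurred phantom recovers RC = 1 for every rod", {
  fx <- iq_vox_coarse()
  img <- simulate_recon_image(fx$vox, NULL, 1e9,
                              degradation_config(scatter_fraction = 0,
                                                 noise = FALSE),
                              system_fwhm = 0)
  uni <- voi_statistics(img, cylindrical_voi(c(0, 0, fx$phantom$uniform_center),
                                             22.5, 10))
  rc <- recovery_coefficients(img, fx$phantom$rods, uni,
                              axial_center = fx$phantom$rod_section_center)
  expect_equal(rc$rc, rep(1, 5), tolerance = 1e-9)
})

test_that("RC rises with rod diameter on a blurred noise-free image", {
  fx <- iq_vox_coarse()
  img <- simulate_recon_image(fx$vox, "Sc-44g", 1e9,
                              degradation_config(scatter_fraction = 0,
                                                 noise = FALSE),
                              system_fwhm = 1.5)
  uni <- voi_statistics(img, cylindrical_voi(c(0, 0, fx$phantom$uniform_center),
                                             22.5, 10))
  rc <- recovery_coefficients(img, fx$phantom$rods, uni,
                              axial_center = fx$phantom$rod_section_center)
  rc <- rc[order(rc$rod_diameter), ]
  expect_true(all(diff(rc$rc) > 0))
  expect_true(all(rc$rc <= 1 + 1e-9))
})

test_that("spill-over ratio and uncertainty follow the defining formula", {
  vals <- array(0, c(3, 3, 3))
  vals[2, 2, ] <- c(4, 5, 6)    # cold VOI: mean 5, sd 1
  img <- manual_image(vals)
  uni <- list(mean = 100, sd = 5)
  sor <- spill_over_ratio(img, cylindrical_voi(c(0, 0, 0), 1.2, 3), uni,
                          region = "water")
  expect_equal(sor$sor, 0.05)
  expect_equal(sor$sigma_sor, 100 * sqrt(0.04 + 0.0025), tolerance = 1e-9)
  # exactly-cold region: SOR 0 with undefined uncertainty
  sor0 <- spill_over_ratio(manual_image(array(0, c(3, 3, 3))),
                           cylindrical_voi(c(0, 0, 0), 1.2, 3), uni)
  expect_equal(sor0$sor, 0)
  expect_true(is.na(sor0$sigma_sor))
})

test_that("scatter correction lowers the spill-over ratio for every nuclide", {
  fx <- iq_vox_coarse()
  for (nm in c("F-18", "Ga-68")) {
    res <- lapply(c(FALSE, TRUE), function(corr) {
      img <- simulate_recon_image(
        fx$vox, nm, 4e9,
        degradation_config(scatter_fraction = 0.2, scatter_corrected = corr,
                           noise = FALSE),
        system_fwhm = 1.5)
      uni <- voi_statistics(img, cylindrical_voi(c(0, 0, fx$phantom$uniform_center),
                                                 22.5, 10))
      w <- fx$phantom$inserts[fx$phantom$inserts$region == "water", ]
      spill_over_ratio(img, cylindrical_voi(c(w$x, w$y, w$z), 4, 7.5), uni)$sor
    })
    expect_lt(res[[2]], res[[1]])
  }
})
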