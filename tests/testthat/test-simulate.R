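# Blur kernels, degradation pipeline, Poisson noise and Gibbs emulation.

test_that("kernels are non-negative and normalized to unit mass", {
  g <- voxel_grid(c(64, 64, 32), 0.4)
  for (nm in c("F-18", "Cu-64", "Sc-44g", "Ga-68")) {
    k <- positron_range_kernel(nm, grid = g)
    expect_true(all(k$values >= 0), info = nm)
    expect_equal(sum(k$values), 1, tolerance = 1e-6, info = nm)
  }
  ks <- system_kernel(1.5, g)
  expect_equal(sum(ks$values), 1, tolerance = 1e-6)
})

test_that("kernel width grows with mean positron energy and inverse density", {
  g <- voxel_grid(c(64, 64, 1), 0.2)
  fw <- vapply(c("F-18", "Cu-64", "Sc-44g", "Ga-68"),
               function(nm) positron_range_kernel(nm, grid = g)$fwhm,
               numeric(1))
  # 249.8 < 278.2 < 632.0 < 836.0 keV mean energies
  expect_true(all(diff(fw) > 0))
  half <- positron_range_kernel("Ga-68", medium_density = 0.5, grid = g)
  full <- positron_range_kernel("Ga-68", medium_density = 1.0, grid = g)
  expect_equal(half$fwhm / full$fwhm, 2, tolerance = 1e-9)
})

test_that("a grid too coarse for the kernel degrades to a delta with a warning", {
  g <- voxel_grid(c(16, 16, 1), 2)
  expect_warning(k <- positron_range_kernel("F-18", grid = g), "delta")
  expect_equal(length(k$values), 1L)
})

test_that("identity degradation returns the input exactly", {
  fx <- derenzo_vox_slab()
  img <- simulate_recon_image(fx$vox, nuclide = NULL, plan = 1e9,
                              config = degradation_config(scatter_fraction = 0,
                                                          noise = FALSE),
                              system_fwhm = 0)
  expect_equal(img$values, fx$vox$activity)
})

test_that("convolution conserves total intensity away from the borders", {
  g <- voxel_grid(c(80, 80, 1), 0.4)
  x <- array(0, c(80, 80, 1))
  x[30:50, 30:50, 1] <- 1        # support well inside the field
  k <- positron_range_kernel("Cu-64", grid = g)
  y <- fft_convolve(x, k)
  expect_equal(sum(y), sum(x), tolerance = 1e-6)
})

test_that("uniform-region counts are Poisson: variance tracks the mean", {
  fx <- iq_vox_coarse()
  cfg <- degradation_config(scatter_fraction = 0.15)
  exp_img <- expected_recon_image(fx$vox, "F-18", cfg, system_fwhm = 1.5)
  img <- add_counting_noise(exp_img, 4.03e9, cfg, seed = 11)
  voi <- cylindrical_voi(c(0, 0, fx$phantom$uniform_center), 22.5, 10)
  scale <- attr(img, "count_scale")
  sel <- petbench:::.voi_voxels(img$grid, voi)
  counts <- as.numeric(img$values[, , sel$z, drop = FALSE][sel$xy]) * scale
  expect_gt(length(counts), 1e4)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.05)
})

test_that("seeded simulations are bit-reproducible", {
  fx <- derenzo_vox_slab()
  cfg <- degradation_config(seed = 42)
  a <- simulate_recon_image(fx$vox, "Ga-68", 1e8, cfg, system_fwhm = 1.5)
  b <- simulate_recon_image(fx$vox, "Ga-68", 1e8, cfg, system_fwhm = 1.5)
  expect_identical(a$values, b$values)
  c <- simulate_recon_image(fx$vox, "Ga-68", 1e8,
                            degradation_config(seed = 43), system_fwhm = 1.5)
  expect_false(identical(b$values, c$values))
})

test_that("scatter correction subtracts the expected background", {
  fx <- iq_vox_coarse()
  cfg_on <- degradation_config(scatter_fraction = 0.2, scatter_corrected = TRUE,
                               noise = FALSE)
  cfg_off <- degradation_config(scatter_fraction = 0.2, noise = FALSE)
  on <- simulate_recon_image(fx$vox, NULL, 1e9, cfg_on, system_fwhm = 0)
  off <- simulate_recon_image(fx$vox, NULL, 1e9, cfg_off, system_fwhm = 0)
  uni_voi <- cylindrical_voi(c(0, 0, fx$phantom$uniform_center), 22.5, 10)
  expect_lt(voi_statistics(on, uni_voi)$mean, voi_statistics(off, uni_voi)$mean)
  # corrected air insert goes back to ~zero (annihilation suppressed + bg removed)
  air_voi <- cylindrical_voi(c(-7.5, 0, fx$phantom$chamber_center), 4, 7.5)
  expect_lt(abs(voi_statistics(on, air_voi)$mean), 1e-6)
})

test_that("gibbs ringing: calibrated overshoot, preserved mean, identity at zero", {
  step <- array(0, c(64, 16, 1))
  step[33:64, , 1] <- 1
  img <- manual_image(step)
  expect_equal(apply_gibbs_ringing(img, 0)$values, step)
  rung <- apply_gibbs_ringing(img, 0.15)
  overshoot <- max(rung$values) - 1
  expect_equal(overshoot, 0.15, tolerance = 0.2 * 0.15)
  expect_equal(mean(rung$values), mean(step), tolerance = 1e-3 * mean(step))
  expect_error(apply_gibbs_ringing(img, -0.1), ">= 0")
})

test_that("NIfTI round trip preserves values and voxel geometry", {
  fx <- iq_vox_coarse()
  img <- simulate_recon_image(fx$vox, "F-18", 1e7,
                              degradation_config(seed = 3), system_fwhm = 1.5)
  path <- tempfile(fileext = ".nii.gz")
  write_recon_image(img, path)
  back <- read_recon_image(path)
  expect_equal(back$values, img$values, tolerance = 1e-6)
  expect_equal(back$grid$voxel_size, img$grid$voxel_size, tolerance = 1e-6)
  unlink(path)
})
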