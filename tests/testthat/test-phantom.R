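# Phantom geometry and voxelization.

test_that("IQ phantom geometry honors the NEMA VOI proportions", {
  ph <- build_iq_phantom()
  expect_equal(0.75 * ph$active_diameter, 22.5)  # uniformity VOI fits
  expect_true(all(abs(ph$inserts$x) + ph$inserts$diameter / 2 <=
                    ph$active_diameter / 2))
  expect_equal(ph$inserts$diameter / 2, c(4, 4))  # cold VOI is 50%
  expect_equal(nrow(ph$rods), 5)
  expect_equal(sort(ph$rods$diameter), 1:5)
  expect_equal(nrow(ph$sections), 3)
})

test_that("IQ phantom rejects impossible rod layouts", {
  expect_error(build_iq_phantom(rod_diameters = c(20, 20)), "overlap|active")
  expect_error(build_iq_phantom(rod_diameters = 18, rod_circle_radius = 7),
               "active region")
  one <- build_iq_phantom(rod_diameters = 5, rod_circle_radius = 0)
  expect_equal(sum(vapply(one$primitives, function(p) p$role == "rod",
                          logical(1))), 1L)
})

test_that("Derenzo sectors obey the twice-diameter spacing rule", {
  ph <- build_derenzo()
  for (sec in ph$sectors) {
    r <- sec$rods
    expect_gte(nrow(r), 3)
    d <- as.matrix(dist(r[, c("x", "y")]))
    diag(d) <- Inf
    expect_equal(min(d), 2 * sec$diameter, tolerance = 1e-9)
    # apex and outer profile endpoints lie on the sector bisector
    expect_false(isTRUE(all.equal(sec$apex, sec$outer)))
  }
  expect_equal(vapply(ph$sectors, `[[`, numeric(1), "diameter"),
               c(2.5, 2.0, 1.5, 1.25, 1.0, 0.8))
  expect_error(build_derenzo(spacing_factor = 0.9), "overlap")
})

test_that("equal-diameter Derenzo construction is 60-degree symmetric", {
  ph <- build_derenzo(diameters = rep(1.5, 6))
  counts <- vapply(ph$sectors, function(s) nrow(s$rods), integer(1))
  expect_true(all(counts == counts[1]))
  # rotating sector 1 rods by 60 degrees reproduces sector 2 rods
  s1 <- ph$sectors[[1]]$rods; s2 <- ph$sectors[[2]]$rods
  th <- pi / 3
  rot <- cbind(s1$x * cos(th) - s1$y * sin(th),
               s1$x * sin(th) + s1$y * cos(th))
  ord1 <- order(round(rot[, 1], 6), round(rot[, 2], 6))
  ord2 <- order(round(s2$x, 6), round(s2$y, 6))
  expect_equal(rot[ord1, 1], s2$x[ord2], tolerance = 1e-9)
  expect_equal(rot[ord1, 2], s2$y[ord2], tolerance = 1e-9)
})

test_that("NEC phantom geometry matches its nominal dimensions", {
  ph <- build_nec_phantom()
  expect_equal(ph$source_offset, 17.5)
  expect_equal(ph$source_length, 140)
  expect_lt(ph$source_offset, ph$phantom_radius)  # source inside phantom
  expect_error(build_nec_phantom(hole_offset = 30), "exits")
})

test_that("voxelization conserves activity against the analytic volume", {
  ph <- build_nec_phantom()   # single active cylinder: analytic volume known
  g <- grid_for_phantom(ph, spacing = 0.4)
  vx <- voxelize(ph, g, supersample = 3)
  analytic <- pi * 1.6^2 * 140
  expect_equal(sum(vx$activity) * prod(g$voxel_size), analytic,
               tolerance = 0.005)
})

test_that("activity total is stable under grid refinement", {
  ph <- build_derenzo()
  t_coarse <- sum(voxelize(ph, grid_for_phantom(ph, spacing = 0.2, nz = 1))$activity) * 0.2^2
  t_fine <- sum(voxelize(ph, grid_for_phantom(ph, spacing = 0.1, nz = 1))$activity) * 0.1^2
  expect_equal(t_coarse, t_fine, tolerance = 0.005)
})

test_that("mu map uses the five segmentation values and stays within bounds", {
  fx <- iq_vox_coarse()
  vx <- fx$vox
  expect_true(all(vx$mu >= 0 & vx$mu <= 0.22 + 1e-12))
  # deep inside the uniform water region mu is exactly 0.095
  g <- vx$grid
  ax <- petbench:::axis_centers
  ix <- which.min(abs(ax(g, 1) - 0))
  iz <- which.min(abs(ax(g, 3) - fx$phantom$uniform_center))
  expect_equal(vx$mu[ix, ix, iz], 0.095)
  # air insert is flagged in the air mask, water insert is not
  ia <- which.min(abs(ax(g, 1) + 7.5))
  iw <- which.min(abs(ax(g, 1) - 7.5))
  icz <- which.min(abs(ax(g, 3) - fx$phantom$chamber_center))
  expect_true(vx$air[ia, ix, icz])
  expect_false(vx$air[iw, ix, icz])
})

test_that("voxelize validates its inputs", {
  ph <- build_iq_phantom()
  expect_error(voxelize(ph, voxel_grid(c(10, 10, 10), 1)), "smaller")
  expect_error(voxelize(ph, grid_for_phantom(ph, spacing = 2), supersample = 0),
               "supersample")
})
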