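# NEMA NU 4-2008 image-quality metrics: uniformity / %SD, recovery
# coefficients with percent uncertainties, and spill-over ratios.
# Voxel-in-VOI rule: a voxel belongs to a cylindrical VOI when its *center*
# lies inside the analytic cylinder. Sample (n-1) standard deviations are
# used throughout.

#' Cylindrical volume of interest
#'
#' @param center VOI center `(x, y, z)` in mm.
#' @param diameter,length Cylinder diameter and axial length in mm.
#' @return A `cylindrical_voi` (axis along z).
#' @export
cylindrical_voi <- function(center, diameter, length) {
  stopifnot(diameter > 0, length > 0, base::length(center) == 3L)
  structure(list(center = as.numeric(center), diameter = diameter,
                 length = length),
            class = "cylindrical_voi")
}

# indices of voxels whose centers fall inside the VOI
.voi_voxels <- function(grid, voi) {
  x <- axis_centers(grid, 1); y <- axis_centers(grid, 2)
  z <- axis_centers(grid, 3)
  inxy <- outer((x - voi$center[1])^2, (y - voi$center[2])^2, `+`) <=
    (voi$diameter / 2)^2
  inz <- abs(z - voi$center[3]) <= voi$length / 2
  list(xy = inxy, z = which(inz))
}

#' Uniform-region statistics (%SD)
#'
#' Mean, extrema and percent standard deviation of the voxels inside a
#' cylindrical VOI; the mean is the uniform-region concentration and the
#' percent standard deviation is the noise metric
#' `%SD = 100 * sd / mean`.
#'
#' @param image A `recon_image`.
#' @param voi A [cylindrical_voi()] (NEMA uniformity default: 75% of the
#'   active diameter, 10 mm long, centered in the uniform section).
#' @return A `uniformity_result` with fields `mean`, `maximum`, `minimum`,
#'   `sd` and `pct_sd`, plus the voxel count `n`.
#' @examples
#' g <- voxel_grid(c(10, 10, 5), 1)
#' img <- petbench:::.recon_image(array(7, c(10, 10, 5)), g)
#' voi_statistics(img, cylindrical_voi(c(0, 0, 0), 6, 4))$pct_sd
#' @export
voi_statistics <- function(image, voi) {
  stopifnot(inherits(image, "recon_image"), inherits(voi, "cylindrical_voi"))
  sel <- .voi_voxels(image$grid, voi)
  if (!length(sel$z) || !any(sel$xy))
    stop("VOI contains no voxel centers", call. = FALSE)
  vals <- as.numeric(image$values[, , sel$z, drop = FALSE][sel$xy])
  m <- mean(vals)
  s <- if (length(vals) > 1) stats::sd(vals) else 0
  if (m == 0 && s > 0)
    stop("%SD undefined: VOI mean is zero with nonzero spread", call. = FALSE)
  structure(list(mean = m, maximum = max(vals), minimum = min(vals),
                 sd = s, pct_sd = if (m == 0) 0 else 100 * s / m,
                 n = length(vals)),
            class = "uniformity_result")
}

#' @export
print.uniformity_result <- function(x, ...) {
  cat(sprintf("<uniformity> mean %.4g [%.4g, %.4g], %%SD = %.3g (n = %d)\n",
              x$mean, x$minimum, x$maximum, x$pct_sd, x$n))
  invisible(x)
}

#' Recovery coefficients from the hot-rod section
#'
#' NEMA-style rod analysis: (1) average the transverse slices across the
#' central axial window into a single 2-D image; (2) for each rod, search a
#' circular ROI of twice the rod diameter around the nominal rod center for
#' the maximum pixel of the averaged image; (3) take the axial profile of the
#' *original* 3-D image at that transverse pixel across the window; (4) the
#' profile mean and standard deviation give
#' `RC = C_rod / C_uniform` and
#' `sigma_RC = 100 * sqrt((STD_rod/C_rod)^2 + (STD_uniform/C_uniform)^2)`.
#' Ties in the maximum search resolve to the lowest (row, column) index.
#'
#' @param image A `recon_image` of the IQ phantom.
#' @param rods Data frame with columns `diameter`, `x`, `y` (e.g.
#'   `phantom$rods` from [build_iq_phantom()]).
#' @param uniform A `uniformity_result` for the uniform region.
#' @param axial_center z position of the rod-section center, mm.
#' @param axial_window Length of the averaged/profiled window, mm (default
#'   10, the central 10 mm of the rods).
#' @param roi_factor ROI diameter in units of rod diameter (default 2).
#' @return Data frame with one row per rod: `rod_diameter`, `c_rod`,
#'   `std_rod`, `rc`, `sigma_rc`.
#' @export
recovery_coefficients <- function(image, rods, uniform, axial_center = 0,
                                  axial_window = 10, roi_factor = 2) {
  stopifnot(inherits(image, "recon_image"),
            all(c("diameter", "x", "y") %in% names(rods)))
  g <- image$grid
  z <- axis_centers(g, 3)
  zsel <- which(abs(z - axial_center) <= axial_window / 2)
  if (!length(zsel)) stop("axial window misses the image", call. = FALSE)
  avg2d <- apply(image$values[, , zsel, drop = FALSE], c(1, 2), mean)
  x <- axis_centers(g, 1); y <- axis_centers(g, 2)
  out <- lapply(seq_len(nrow(rods)), function(i) {
    r_roi <- roi_factor * rods$diameter[i] / 2
    roi <- outer((x - rods$x[i])^2, (y - rods$y[i])^2, `+`) <= r_roi^2
    if (!any(roi)) stop("rod ROI contains no pixels", call. = FALSE)
    if (any(roi[1, ]) || any(roi[nrow(roi), ]) ||
        any(roi[, 1]) || any(roi[, ncol(roi)]))
      stop("rod ROI extends off the image", call. = FALSE)
    masked <- ifelse(roi, avg2d, -Inf)
    peak <- which(masked == max(masked), arr.ind = TRUE)
    peak <- peak[order(peak[, 1], peak[, 2]), , drop = FALSE][1, ]
    profile <- image$values[peak[1], peak[2], zsel]
    c_rod <- mean(profile)
    std_rod <- stats::sd(profile)
    if (c_rod == 0) stop("rod mean is zero; sigma_RC undefined", call. = FALSE)
    data.frame(rod_diameter = rods$diameter[i], c_rod = c_rod,
               std_rod = std_rod, rc = c_rod / uniform$mean,
               sigma_rc = 100 * sqrt((std_rod / c_rod)^2 +
                                       (uniform$sd / uniform$mean)^2))
  })
  do.call(rbind, out)
}

#' Spill-over ratio of a cold insert
#'
#' `SOR = C_cold / C_uniform` with
#' `sigma_SOR = 100 * sqrt((STD_cold/C_cold)^2 + (STD_uniform/C_uniform)^2)`.
#' A cold region measuring exactly zero yields `SOR = 0` with `sigma_sor`
#' flagged `NA` (undefined).
#'
#' @param image A `recon_image`.
#' @param cold_voi A [cylindrical_voi()] centered in the insert (NEMA
#'   default: half the insert diameter, 7.5 mm long).
#' @param uniform A `uniformity_result` for the uniform region.
#' @param region Label (`"water"` or `"air"`) carried into the result.
#' @return One-row data frame: `region`, `c_cold`, `std_cold`, `sor`,
#'   `sigma_sor`.
#' @export
spill_over_ratio <- function(image, cold_voi, uniform, region = NA_character_) {
  st <- voi_statistics(image, cold_voi)
  if (st$mean == 0) {
    return(data.frame(region = region, c_cold = 0, std_cold = st$sd, sor = 0,
                      sigma_sor = NA_real_))
  }
  data.frame(region = region, c_cold = st$mean, std_cold = st$sd,
             sor = st$mean / uniform$mean,
             sigma_sor = 100 * sqrt((st$sd / st$mean)^2 +
                                      (uniform$sd / uniform$mean)^2))
}
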