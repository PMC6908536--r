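#' Voxel grid geometry
#'
#' Regular 3-D grid describing a simulated or reconstructed volume. The grid
#' origin is the position (mm) of the grid *corner*; voxel centers sit at
#' `origin + (i - 0.5) * voxel_size`. The z axis is the scanner axis. With
#' `shape[3] == 1` the grid describes a single transverse slab and the
#' simulator operates in-plane.
#'
#' @param shape Integer vector `(nx, ny, nz)`.
#' @param voxel_size Voxel edge lengths `(dx, dy, dz)` in mm; a scalar is
#'   recycled isotropically.
#' @param origin Corner position in mm; default centers the grid on the
#'   scanner axis at (0, 0, 0).
#' @return A `voxel_grid` object.
#' @examples
#' voxel_grid(c(100, 100, 60), 0.4)
#' @export
voxel_grid <- function(shape, voxel_size, origin = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(origin)) origin <- -shape * voxel_size / 2
  stopifnot(length(origin) == 3L)
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d @ %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

# voxel-center coordinates along one axis (1 = x, 2 = y, 3 = z)
axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$voxel_size[axis]
}

voxel_volume <- function(grid) prod(grid$voxel_size)

#' Grid sized to enclose a phantom
#'
#' Convenience constructor: a grid centered on the phantom with the given
#' spacing and a margin on every side.
#'
#' @param phantom A `phantom_model`.
#' @param spacing Isotropic voxel size, mm (default 0.2).
#' @param margin Extra space beyond the phantom bounding box on each side, mm.
#' @param nz Optional fixed number of slices (e.g. `1` for slab mode);
#'   overrides the axial extent implied by the phantom.
#' @return A [voxel_grid()].
#' @export
grid_for_phantom <- function(phantom, spacing = 0.2, margin = 2, nz = NULL) {
  bb <- phantom$bounding_box  # list(xy_radius, z_range)
  half_xy <- bb$xy_radius + margin
  n_xy <- 2L * as.integer(ceiling(half_xy / spacing))
  if (is.null(nz)) {
    z0 <- bb$z_range[1] - margin
    z1 <- bb$z_range[2] + margin
    nz <- as.integer(ceiling((z1 - z0) / spacing))
    origin_z <- (z0 + z1) / 2 - nz * spacing / 2
  } else {
    nz <- as.integer(nz)
    origin_z <- mean(bb$z_range) - nz * spacing / 2
  }
  voxel_grid(c(n_xy, n_xy, nz), spacing,
             origin = c(-n_xy * spacing / 2, -n_xy * spacing / 2, origin_z))
}
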