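# Parametric phantom models: z-aligned cylindrical primitives painted in order
# (later primitives override earlier ones), rasterized with sub-voxel
# supersampling into activity and attenuation (mu) grids.

# linear attenuation coefficients at 511 keV for the five segmentation classes
# (cm^-1); PMMA and HDPE phantom bodies are water-equivalent at segmentation.
.mu_values <- c(background = 0.00, bed = 0.0150, water = 0.095,
                bone = 0.1780, aluminum = 0.22, air = 0.00,
                pmma = 0.095, hdpe = 0.095)

.primitive <- function(center, diameter, length, material, activity,
                       role = "fill") {
  stopifnot(diameter > 0, length > 0, activity >= 0,
            material %in% names(.mu_values))
  list(center = as.numeric(center), diameter = diameter, length = length,
       material = material, activity = activity, role = role)
}

.phantom_model <- function(name, primitives, bounding_box, extra = list()) {
  structure(c(list(name = name, primitives = primitives,
                   bounding_box = bounding_box), extra),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf("<phantom_model> %s: %d primitives, r = %.3g mm, z in [%.3g, %.3g] mm\n",
              x$name, length(x$primitives), x$bounding_box$xy_radius,
              x$bounding_box$z_range[1], x$bounding_box$z_range[2]))
  invisible(x)
}

#' NEMA NU 4-2008 image-quality phantom
#'
#' Three axial sections: a rod section (five fillable rods drilled in solid
#' PMMA), a uniformly fillable region, and a section holding two cold-insert
#' chambers (one water-filled, one air-filled) surrounded by activity. Rod and
#' uniform activity concentrations are equal. Dimensions default to the
#' nominal NU 4-2008 phantom and are all overridable.
#'
#' @param active_diameter Diameter of the fillable region, mm (default 30).
#' @param rod_diameters Fillable rod diameters, mm (default 1:5).
#' @param insert_diameter Inner diameter of the cold chambers, mm (default 8).
#' @param rod_length,uniform_length,chamber_length Axial lengths of the three
#'   sections, mm.
#' @param rod_circle_radius Radius at which the rod centers sit, mm.
#' @param insert_offset Distance of each chamber center from the axis, mm.
#' @param body_diameter Outer diameter of the PMMA body, mm.
#' @param activity Activity concentration of the fillable regions (relative
#'   units).
#' @return A `phantom_model`; `$rods` lists rod centers, `$sections` the
#'   z-range of each section, `$inserts` the cold-chamber centers.
#' @examples
#' ph <- build_iq_phantom()
#' ph$sections
#' @export
build_iq_phantom <- function(active_diameter = 30,
                             rod_diameters = c(1, 2, 3, 4, 5),
                             insert_diameter = 8,
                             rod_length = 20, uniform_length = 15,
                             chamber_length = 15,
                             rod_circle_radius = 7, insert_offset = 7.5,
                             body_diameter = 33.5, activity = 1) {
  total <- rod_length + uniform_length + chamber_length
  z0 <- -total / 2
  sections <- data.frame(
    section = c("rod", "uniform", "chamber"),
    z_min = z0 + c(0, rod_length, rod_length + uniform_length),
    z_max = z0 + c(rod_length, rod_length + uniform_length, total))
  mid <- function(s) mean(unlist(sections[sections$section == s, c("z_min", "z_max")]))

  nrod <- length(rod_diameters)
  ang <- 2 * pi * (seq_len(nrod) - 1) / nrod
  rods <- data.frame(diameter = rod_diameters,
                     x = rod_circle_radius * cos(ang),
                     y = rod_circle_radius * sin(ang))
  # geometry checks: rods inside the active region and mutually disjoint
  if (any(rod_circle_radius + rods$diameter / 2 > active_diameter / 2))
    stop("rod exits the active region", call. = FALSE)
  if (nrod > 1) {
    for (i in seq_len(nrod - 1)) for (j in (i + 1):nrod) {
      d <- sqrt((rods$x[i] - rods$x[j])^2 + (rods$y[i] - rods$y[j])^2)
      if (d < (rods$diameter[i] + rods$diameter[j]) / 2)
        stop("rods overlap", call. = FALSE)
    }
  }
  if (insert_offset + insert_diameter / 2 > active_diameter / 2)
    stop("cold insert exits the active region", call. = FALSE)

  prim <- list(.primitive(c(0, 0, 0), body_diameter, total, "pmma", 0,
                          role = "body"))
  for (i in seq_len(nrod))
    prim <- c(prim, list(.primitive(c(rods$x[i], rods$y[i], mid("rod")),
                                    rods$diameter[i], rod_length,
                                    "water", activity, role = "rod")))
  prim <- c(prim, list(
    .primitive(c(0, 0, mid("uniform")), active_diameter, uniform_length,
               "water", activity, role = "fill"),
    .primitive(c(0, 0, mid("chamber")), active_diameter, chamber_length,
               "water", activity, role = "fill"),
    .primitive(c(insert_offset, 0, mid("chamber")), insert_diameter,
               chamber_length, "water", 0, role = "insert"),
    .primitive(c(-insert_offset, 0, mid("chamber")), insert_diameter,
               chamber_length, "air", 0, role = "insert")))

  inserts <- data.frame(region = c("water", "air"),
                        x = c(insert_offset, -insert_offset), y = 0,
                        z = mid("chamber"), diameter = insert_diameter)
  .phantom_model("nema_iq", prim,
                 list(xy_radius = body_diameter / 2, z_range = c(z0, z0 + total)),
                 extra = list(rods = rods, sections = sections,
                              inserts = inserts,
                              active_diameter = active_diameter,
                              rod_section_center = mid("rod"),
                              uniform_center = mid("uniform"),
                              chamber_center = mid("chamber")))
}

#' Derenzo resolution phantom
#'
#' Six 60-degree sectors of fillable rods in a PMMA disc; within each sector
#' the rods form a triangular lattice with center-to-center spacing equal to
#' `spacing_factor` times the rod diameter (twice by convention). Rows grow
#' outward from an apex rod near the phantom center; every second row has a
#' rod on the sector bisector, and the outermost such rod is the profile
#' endpoint used by the contrast analysis.
#'
#' @param diameters Rod diameter of each sector, mm.
#' @param spacing_factor Center-to-center spacing in units of rod diameter
#'   (default 2; values below 1 would overlap rods and are rejected).
#' @param rod_length Axial rod length, mm.
#' @param disc_diameter Diameter of the fillable field, mm.
#' @param body_diameter Outer PMMA body diameter, mm.
#' @param r_inner Radius of each sector's apex rod; default `1.5 * diameter`.
#' @param r_max Maximum rod-center radius, mm.
#' @param activity Rod activity concentration (relative units).
#' @return A `phantom_model`; `$sectors` holds, per sector, the rod centers
#'   and the apex/outer profile endpoints.
#' @examples
#' dz <- build_derenzo()
#' sapply(dz$sectors, function(s) nrow(s$rods))
#' @export
build_derenzo <- function(diameters = c(2.5, 2.0, 1.5, 1.25, 1.0, 0.8),
                          spacing_factor = 2, rod_length = 10,
                          disc_diameter = 30, body_diameter = 34,
                          r_inner = NULL, r_max = 12.5, activity = 1) {
  if (spacing_factor < 1)
    stop("spacing_factor < 1 places rods closer than one diameter: rods overlap",
         call. = FALSE)
  nsec <- length(diameters)
  prim <- list(.primitive(c(0, 0, 0), body_diameter, rod_length, "pmma", 0,
                          role = "body"))
  sectors <- vector("list", nsec)
  for (k in seq_len(nsec)) {
    d <- diameters[k]
    spacing <- spacing_factor * d
    r0 <- if (is.null(r_inner)) 1.5 * d else r_inner
    theta <- 2 * pi * (k - 0.5) / nsec   # sector bisector azimuth
    u <- c(cos(theta), sin(theta))       # radial direction
    v <- c(-sin(theta), cos(theta))      # tangential direction
    rows <- list(); i <- 0
    repeat {
      ri <- r0 + i * spacing * sqrt(3) / 2
      if (ri > r_max) break
      off <- (seq_len(i + 1) - 1 - i / 2) * spacing
      xy <- cbind(u[1] * ri + v[1] * off, u[2] * ri + v[2] * off)
      keep <- sqrt(rowSums(xy^2)) <= min(r_max, disc_diameter / 2 - d / 2 - 0.5)
      rows[[i + 1]] <- cbind(xy[keep, , drop = FALSE], row = i)
      i <- i + 1
    }
    rods <- do.call(rbind, rows)
    rods <- data.frame(x = rods[, 1], y = rods[, 2], row = rods[, 3])
    # bisector rods: odd-count rows (even row index) have one on the bisector
    on_bisector <- abs(rods$x * v[1] + rods$y * v[2]) < 1e-9
    bis <- rods[on_bisector, ]
    apex <- bis[which.min(bis$row), c("x", "y")]
    outer <- bis[which.max(bis$row), c("x", "y")]
    sectors[[k]] <- list(diameter = d, rods = rods,
                         apex = as.numeric(apex), outer = as.numeric(outer))
    for (r in seq_len(nrow(rods)))
      prim <- c(prim, list(.primitive(c(rods$x[r], rods$y[r], 0), d,
                                      rod_length, "water", activity,
                                      role = "rod")))
  }
  .phantom_model("derenzo", prim,
                 list(xy_radius = body_diameter / 2,
                      z_range = c(-rod_length / 2, rod_length / 2)),
                 extra = list(sectors = sectors, diameters = diameters))
}

#' NEC ("rat"-size) count-rate phantom
#'
#' High-density polyethylene cylinder, 50 mm diameter by 150 mm long, with a
#' 3.2 mm hole parallel to and 17.5 mm from the axis carrying a 140-mm line
#' source.
#'
#' @param diameter,length Phantom dimensions, mm.
#' @param hole_diameter Source hole diameter, mm.
#' @param hole_offset Hole center distance from the axis, mm.
#' @param source_length Line-source length, mm.
#' @param activity Line-source activity (relative units).
#' @return A `phantom_model`; `$source_offset` is used by the sinogram
#'   simulator.
#' @export
build_nec_phantom <- function(diameter = 50, length = 150,
                              hole_diameter = 3.2, hole_offset = 17.5,
                              source_length = 140, activity = 1) {
  if (hole_offset + hole_diameter / 2 >= diameter / 2)
    stop("source hole exits the phantom", call. = FALSE)
  prim <- list(
    .primitive(c(0, 0, 0), diameter, length, "hdpe", 0, role = "body"),
    .primitive(c(hole_offset, 0, 0), hole_diameter, length, "air", 0,
               role = "insert"),
    .primitive(c(hole_offset, 0, 0), hole_diameter, source_length, "water",
               activity, role = "source"))
  .phantom_model("nec", prim,
                 list(xy_radius = diameter / 2, z_range = c(-length / 2, length / 2)),
                 extra = list(source_offset = hole_offset,
                              source_length = source_length,
                              source_diameter = hole_diameter,
                              phantom_radius = diameter / 2))
}

# fractional in-plane coverage of a disc over every pixel of the grid,
# estimated with an s x s sub-pixel sample
.coverage_xy <- function(grid, cx, cy, radius, supersample) {
  x <- axis_centers(grid, 1); y <- axis_centers(grid, 2)
  dx <- grid$voxel_size[1]; dy <- grid$voxel_size[2]
  s <- supersample
  off <- ((seq_len(s) - 0.5) / s - 0.5)
  cov <- matrix(0, length(x), length(y))
  r2 <- radius^2
  for (ox in off) {
    xs <- (x + ox * dx - cx)^2
    for (oy in off) {
      ys <- (y + oy * dy - cy)^2
      cov <- cov + (outer(xs, ys, `+`) <= r2)
    }
  }
  cov / s^2
}

# exact fractional axial overlap of [z0, z1] with each slice
.coverage_z <- function(grid, z0, z1) {
  z <- axis_centers(grid, 3); dz <- grid$voxel_size[3]
  pmin(pmax((pmin(z1, z + dz / 2) - pmax(z0, z - dz / 2)) / dz, 0), 1)
}

#' Rasterize a phantom into activity and attenuation volumes
#'
#' Primitives are painted in order with sub-voxel-coverage weighting: each
#' voxel's activity and mu are coverage-weighted blends, giving anti-aliased
#' (partial-volume) edges. Axial coverage is computed analytically, in-plane
#' coverage by `supersample^2` sub-pixel sampling.
#'
#' @param phantom A `phantom_model`.
#' @param grid A [voxel_grid()] enclosing the phantom (in-plane; the axial
#'   extent may crop the phantom, e.g. in slab mode).
#' @param supersample Sub-pixel samples per axis (default 3).
#' @return A list of class `voxel_phantom` with elements `activity` and `mu`
#'   (3-D arrays on `grid`), `grid`, and logical masks `support` (inside the
#'   phantom body) and `air` (air-filled interior regions).
#' @examples
#' ph <- build_nec_phantom()
#' vx <- voxelize(ph, grid_for_phantom(ph, spacing = 1), supersample = 2)
#' sum(vx$activity > 0) > 0
#' @export
voxelize <- function(phantom, grid, supersample = 3) {
  stopifnot(inherits(phantom, "phantom_model"), inherits(grid, "voxel_grid"))
  supersample <- as.integer(supersample)
  if (supersample < 1) stop("supersample must be >= 1", call. = FALSE)
  half_fov <- grid$shape[1:2] * grid$voxel_size[1:2] / 2
  if (phantom$bounding_box$xy_radius > min(half_fov) + 1e-9)
    stop("grid transverse field of view is smaller than the phantom", call. = FALSE)
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  act <- array(0, c(nx, ny, nz))
  mu <- array(0, c(nx, ny, nz))
  support <- array(0, c(nx, ny, nz))
  airfrac <- array(0, c(nx, ny, nz))
  for (p in phantom$primitives) {
    cov_xy <- .coverage_xy(grid, p$center[1], p$center[2], p$diameter / 2,
                           supersample)
    cov_z <- if (nz == 1L) 1 else
      .coverage_z(grid, p$center[3] - p$length / 2, p$center[3] + p$length / 2)
    for (k in seq_len(nz)) {
      if (length(cov_z) > 1 && cov_z[k] == 0) next
      f <- cov_xy * (if (length(cov_z) == 1) cov_z else cov_z[k])
      act[, , k] <- act[, , k] * (1 - f) + p$activity * f
      mu[, , k] <- mu[, , k] * (1 - f) + .mu_values[[p$material]] * f
      if (p$role %in% c("body", "fill"))
        support[, , k] <- pmax(support[, , k], f)
      airfrac[, , k] <- airfrac[, , k] * (1 - f) +
        (p$material == "air") * f
    }
  }
  structure(list(activity = act, mu = mu, grid = grid,
                 support = support > 0.5, air = airfrac > 0.5,
                 phantom = phantom),
            class = "voxel_phantom")
}
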