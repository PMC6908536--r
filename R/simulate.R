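# Image-domain degradation simulator: instead of reprojecting and
# reconstructing, the pipeline degrades the voxelized activity directly with
# the structure the downstream metrics assume -- positron-range blur, system
# (detector + reconstruction) blur, a scatter/spill background, Poisson
# counting noise scaled to the decay-equalized count budget, and optional
# edge ringing.

#' Degradation configuration
#'
#' @param scatter_fraction Fraction of recorded counts that are
#'   scatter/spurious background, in \[0, 1) (default 0.15).
#' @param scatter_corrected If `TRUE`, the *expected* background field is
#'   subtracted from the noisy image (the correction removes the mean, not
#'   the realization, as a scatter estimate would).
#' @param noise Draw Poisson counting noise (default `TRUE`).
#' @param detection_efficiency Recorded coincidences per positron decay
#'   (default 0.02; only relative quantities are asserted downstream).
#' @param air_annihilation_fraction Probability scale applied to annihilations
#'   placed inside air-filled regions; positrons ranging into air mostly
#'   traverse it, so the default is the air/water density ratio (~1.2e-3).
#' @param gibbs_ringing Apply edge ringing emulation ([apply_gibbs_ringing()]).
#' @param gibbs_amplitude Relative over/undershoot amplitude.
#' @param seed Integer seed for the Poisson draw (`NULL` leaves the RNG
#'   state alone).
#' @return A `degradation_config`.
#' @export
degradation_config <- function(scatter_fraction = 0.15,
                               scatter_corrected = FALSE,
                               noise = TRUE,
                               detection_efficiency = 0.02,
                               air_annihilation_fraction = 0.0012,
                               gibbs_ringing = FALSE,
                               gibbs_amplitude = 0.1,
                               seed = NULL) {
  if (scatter_fraction < 0 || scatter_fraction >= 1)
    stop("scatter_fraction must lie in [0, 1)", call. = FALSE)
  stopifnot(detection_efficiency > 0, gibbs_amplitude >= 0,
            air_annihilation_fraction >= 0)
  structure(list(scatter_fraction = scatter_fraction,
                 scatter_corrected = scatter_corrected,
                 noise = noise,
                 detection_efficiency = detection_efficiency,
                 air_annihilation_fraction = air_annihilation_fraction,
                 gibbs_ringing = gibbs_ringing,
                 gibbs_amplitude = gibbs_amplitude,
                 seed = seed),
            class = "degradation_config")
}

.recon_image <- function(values, grid, provenance = list()) {
  structure(list(values = values, grid = grid, provenance = provenance),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %s, mean %.4g, range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = "x"), mean(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Noise-free expected reconstructed image
#'
#' The deterministic part of the simulator: positron-range and system blur,
#' suppression of annihilations inside air cavities, and the uniform scatter
#' background over the phantom support. The result is in activity
#' concentration units and is what the Poisson stage scales to counts. It
#' depends on the nuclide but not on the acquisition plan or seed, so it can
#' be computed once and reused across count budgets and noise realizations.
#'
#' @param vox A `voxel_phantom` from [voxelize()].
#' @param nuclide A [radionuclide()] or name (determines the positron-range
#'   kernel); `NULL` skips positron blurring.
#' @param config A [degradation_config()].
#' @param system_fwhm System/reconstruction blur FWHM in mm.
#' @param ... Passed to [positron_range_kernel()].
#' @return A `recon_image` with attributes `background` (scalar expected
#'   background level) and `support`/`n_support` used by the noise stage.
#' @export
expected_recon_image <- function(vox, nuclide, config = degradation_config(),
                                 system_fwhm = 1.5, ...) {
  stopifnot(inherits(vox, "voxel_phantom"))
  kernels <- list()
  nuc_name <- NULL
  if (!is.null(nuclide)) {
    nuclide <- .as_nuclide(nuclide)
    nuc_name <- nuclide$name
    kernels <- c(kernels, list(positron_range_kernel(nuclide, grid = vox$grid, ...)))
  }
  if (system_fwhm > 0)
    kernels <- c(kernels, list(system_kernel(system_fwhm, vox$grid)))
  blurred <- if (length(kernels)) fft_convolve(vox$activity, kernels) else
    vox$activity
  blurred[blurred < 0] <- 0
  if (any(vox$air))
    blurred[vox$air] <- blurred[vox$air] * config$air_annihilation_fraction
  n_support <- sum(vox$support)
  sf <- config$scatter_fraction
  background <- if (sf > 0 && n_support > 0)
    (sf / (1 - sf)) * sum(blurred) / n_support else 0
  expected <- blurred
  expected[vox$support] <- expected[vox$support] + background
  img <- .recon_image(expected, vox$grid,
                      provenance = list(nuclide = nuc_name,
                                        system_fwhm = system_fwhm,
                                        config = config))
  attr(img, "background") <- background
  attr(img, "support") <- vox$support
  img
}

#' Poisson counting-noise stage
#'
#' Scales an expected image so that its total equals the detected-count
#' budget, draws independent Poisson counts per voxel, and rescales back to
#' concentration units; optionally subtracts the expected background field
#' (scatter correction).
#'
#' @param expected A `recon_image` from [expected_recon_image()].
#' @param plan An [acquisition_plan()] supplying the positron-decay budget,
#'   or a bare count of positron decays.
#' @param config A [degradation_config()]; `config$seed` (overridden by
#'   `seed`) makes the draw reproducible.
#' @param seed Optional integer seed taking precedence over `config$seed`.
#' @return A `recon_image` in concentration units, with attribute
#'   `count_scale` (counts per concentration unit).
#' @export
add_counting_noise <- function(expected, plan, config = degradation_config(),
                               seed = NULL) {
  stopifnot(inherits(expected, "recon_image"))
  n_decays <- if (inherits(plan, "acquisition_plan"))
    plan$expected_positron_decays else as.numeric(plan)
  total <- sum(expected$values)
  if (total <= 0) stop("expected image has no activity", call. = FALSE)
  scale <- config$detection_efficiency * n_decays / total
  vals <- expected$values
  if (config$noise) {
    if (n_decays <= 0)
      stop("plan must contain positron decays for a noisy simulation", call. = FALSE)
    seed <- if (!is.null(seed)) seed else config$seed
    if (!is.null(seed)) set.seed(seed)
    vals <- array(stats::rpois(length(vals), vals * scale) / scale, dim(vals))
  }
  if (config$scatter_corrected) {
    bg <- attr(expected, "background")
    if (!is.null(bg) && bg > 0) {
      supp <- attr(expected, "support")
      vals[supp] <- vals[supp] - bg
    }
  }
  img <- .recon_image(vals, expected$grid,
                      provenance = c(expected$provenance,
                                     list(positron_decays = n_decays,
                                          seed = seed)))
  attr(img, "count_scale") <- scale
  img
}

#' Simulate a pseudo-reconstructed phantom image
#'
#' One-call pipeline: [expected_recon_image()] then [add_counting_noise()],
#' then optional [apply_gibbs_ringing()]. Runs with the same seed are
#' identical.
#'
#' @inheritParams expected_recon_image
#' @inheritParams add_counting_noise
#' @examples
#' ph <- build_nec_phantom()
#' vx <- voxelize(ph, grid_for_phantom(ph, spacing = 1, nz = 1))
#' img <- simulate_recon_image(vx, "F-18", acquisition_plan("F-18", 3.7e6, 60),
#'                             degradation_config(seed = 1), system_fwhm = 2)
#' @export
simulate_recon_image <- function(vox, nuclide, plan,
                                 config = degradation_config(),
                                 system_fwhm = 1.5, seed = NULL, ...) {
  expected <- expected_recon_image(vox, nuclide, config, system_fwhm, ...)
  img <- add_counting_noise(expected, plan, config, seed)
  if (config$gibbs_ringing)
    img <- apply_gibbs_ringing(img, config$gibbs_amplitude)
  img
}

#' Edge-ringing (Gibbs phenomenon) emulation
#'
#' Adds over/undershoot at sharp activity transitions, as produced by
#' band-limited or resolution-modelled reconstruction, via an unsharp mask
#' whose gain is calibrated analytically so that a step edge of height h
#' overshoots by `amplitude * h` at the voxel adjacent to the edge. The image
#' mean is preserved exactly (the smoothing is DC-neutral).
#'
#' @param image A `recon_image` (or bare array).
#' @param amplitude Relative overshoot amplitude (0 = identity).
#' @param sigma_vox Standard deviation of the smoothing Gaussian in voxels.
#' @return Object of the same type as `image`.
#' @export
apply_gibbs_ringing <- function(image, amplitude, sigma_vox = 3) {
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  vals <- if (inherits(image, "recon_image")) image$values else image
  if (amplitude > 0) {
    d <- dim(vals)
    # separable Gaussian smoothing via circular FFT (exactly DC-preserving):
    # the n-D transfer function is the outer product of per-axis transfers
    transfer <- lapply(d, function(n) {
      if (n < 4) return(rep(1 + 0i, n))
      x <- c(0:(n %/% 2), if (n > 1) -((n - n %/% 2 - 1):1))
      g <- exp(-x^2 / (2 * sigma_vox^2)); g <- g / sum(g)
      fft(g)
    })
    tf <- outer(outer(transfer[[1]], transfer[[2]]), transfer[[3]])
    smooth <- Re(fft(fft(vals) * array(tf, d), inverse = TRUE)) / prod(d)
    # step response of (1 - G) at the first voxel center, half a voxel in
    # from the edge, fixes the gain for the requested overshoot
    gain <- amplitude / (1 - stats::pnorm(0.5 / sigma_vox))
    vals <- vals + gain * (vals - smooth)
  }
  if (inherits(image, "recon_image")) {
    image$values <- vals
    image
  } else vals
}

#' Write a simulated volume to NIfTI
#'
#' @param image A `recon_image` or `voxel_phantom` component (bare array plus
#'   a grid).
#' @param path Output `.nii`/`.nii.gz` path.
#' @param grid Required when `image` is a bare array.
#' @return `path`, invisibly.
#' @export
write_recon_image <- function(image, path, grid = NULL) {
  if (inherits(image, "recon_image")) {
    vals <- image$values; grid <- image$grid
  } else vals <- image
  stopifnot(inherits(grid, "voxel_grid"))
  nii <- RNifti::asNifti(vals)
  # single-slice volumes are stored 2-D; only the in-plane spacing survives
  RNifti::pixdim(nii) <- grid$voxel_size[seq_along(dim(nii))]
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a reconstructed volume from NIfTI
#'
#' The voxel spacing is taken from the header; the grid is centered on the
#' volume (phantom-centric convention used throughout).
#'
#' @param path NIfTI file path.
#' @return A `recon_image`.
#' @export
read_recon_image <- function(path) {
  nii <- RNifti::readNifti(path)
  vals <- array(as.numeric(nii), dim(nii))
  vs <- RNifti::pixdim(nii)
  if (length(vs) < 3) vs <- c(vs, rep(1, 3 - length(vs)))
  if (length(dim(vals)) == 2) dim(vals) <- c(dim(vals), 1)
  .recon_image(vals, voxel_grid(dim(vals), vs[1:3]),
               provenance = list(source = path))
}
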