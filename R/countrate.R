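# Count-rate study machinery: parametric trues/scatter/randoms/spurious rate
# model over a decaying source, synthetic 2-D sinograms, NU-4-style rate
# extraction, NECR, and the quadratic randoms fit.
#
# Activities in this module are in MBq; rates in counts/s.

#' Count-rate model parameters
#'
#' @param sensitivity Trues recorded per positron decay in the absence of
#'   dead time.
#' @param scatter_fraction Scatter fraction SF = R_S / (R_S + R_T) of the
#'   annihilation radiation, in \[0, 1).
#' @param randoms_coefficient Random-coincidence rate per MBq^2 (randoms grow
#'   with the square of the singles rate).
#' @param dead_time Paralyzable dead-time constant, s: trues are attenuated
#'   by `exp(-R_ideal * dead_time)`.
#' @param spurious_coefficient Spurious-coincidence rate per MBq per unit
#'   prompt-gamma yield (the in-window detection of prompt gammas is not
#'   separable from scatter/randoms; only its direction matters).
#' @param spurious_random_share Fraction of the spurious load behaving like
#'   randoms (activity-squared, per MBq^2 per unit yield); the remainder is
#'   scatter-like.
#' @return A `rate_model_params`.
#' @export
rate_model_params <- function(sensitivity = 0.05,
                              scatter_fraction = 0.30,
                              randoms_coefficient = 60,
                              dead_time = 2e-7,
                              spurious_coefficient = 2000,
                              spurious_random_share = 0.5) {
  if (scatter_fraction < 0 || scatter_fraction >= 1)
    stop("scatter_fraction must lie in [0, 1)", call. = FALSE)
  stopifnot(sensitivity >= 0, randoms_coefficient >= 0, dead_time >= 0,
            spurious_coefficient >= 0,
            spurious_random_share >= 0, spurious_random_share <= 1)
  structure(list(sensitivity = sensitivity,
                 scatter_fraction = scatter_fraction,
                 randoms_coefficient = randoms_coefficient,
                 dead_time = dead_time,
                 spurious_coefficient = spurious_coefficient,
                 spurious_random_share = spurious_random_share),
            class = "rate_model_params")
}

#' Frame schedule for a decaying source
#'
#' Frames are constant-duration and must not exceed a quarter of the
#' half-life: 30 min where the half-life allows (44gSc), otherwise 15 min
#' (18F, 68Ga). Framing runs until the activity falls below `stop_activity`.
#'
#' @param nuclide A [radionuclide()] or name.
#' @param start_activity Starting activity, MBq.
#' @param stop_activity Activity at which framing stops, MBq.
#' @param frame_duration Override the frame duration, s.
#' @return Data frame with `t_start`, `t_mid`, `t_end` (s) and `activity`
#'   (MBq at frame midpoint).
#' @export
frame_schedule <- function(nuclide, start_activity = 100, stop_activity = 1.5,
                           frame_duration = NULL) {
  nuclide <- .as_nuclide(nuclide)
  if (is.null(frame_duration))
    frame_duration <- if (nuclide$half_life / 4 >= 1800) 1800 else 900
  if (frame_duration > nuclide$half_life / 4)
    warning("frame duration exceeds a quarter of the half-life")
  span <- decay_time(nuclide, start_activity, stop_activity)
  n <- max(1L, floor(span / frame_duration))
  t0 <- (seq_len(n) - 1) * frame_duration
  tm <- t0 + frame_duration / 2
  data.frame(t_start = t0, t_mid = tm, t_end = t0 + frame_duration,
             activity = start_activity * 2^(-tm / nuclide$half_life))
}

#' Ground-truth event rates over a decaying source
#'
#' Parametric rate model evaluated at a set of activities:
#' \itemize{
#'   \item trues `R_T = sensitivity * BR * A * exp(-R_ideal * dead_time)`
#'     (paralyzable dead time on the ideal trues rate),
#'   \item scatter `R_S = SF/(1-SF) * R_T` plus the scatter-like share of the
#'     spurious load `(1-rho) * c_sp * A * Y`,
#'   \item randoms `R_R = k_R * A^2` plus the random-like spurious share
#'     `rho * c_sp/100 * A^2 * Y`,
#' }
#' where `A` is activity in MBq, `Y` the summed prompt-gamma yield, and all
#' rates vanish as `A -> 0`.
#'
#' @param nuclide A [radionuclide()] or name.
#' @param activities Activities at which to evaluate, MBq; alternatively
#'   supply `frames` from [frame_schedule()].
#' @param params A [rate_model_params()].
#' @param frames Optional frame schedule whose midpoint activities are used.
#' @return Data frame of `rate_points`: `activity`, `r_true`, `r_scatter`,
#'   `r_random`, `necr`.
#' @export
simulate_rates <- function(nuclide, activities = NULL,
                           params = rate_model_params(), frames = NULL) {
  nuclide <- .as_nuclide(nuclide)
  if (is.null(activities)) {
    if (is.null(frames)) stop("supply activities or frames", call. = FALSE)
    activities <- frames$activity
  }
  if (any(activities < 0)) stop("activities must be >= 0", call. = FALSE)
  a_bq <- activities * 1e6
  gamma_yield <- sum(nuclide$prompt_gammas$yield)
  r_ideal <- params$sensitivity * nuclide$positron_branching * a_bq
  r_true <- r_ideal * exp(-r_ideal * params$dead_time)
  sf <- params$scatter_fraction
  r_scatter <- sf / (1 - sf) * r_true +
    (1 - params$spurious_random_share) * params$spurious_coefficient *
    activities * gamma_yield
  r_random <- params$randoms_coefficient * activities^2 +
    params$spurious_random_share * params$spurious_coefficient / 100 *
    activities^2 * gamma_yield
  data.frame(activity = activities, r_true = r_true, r_scatter = r_scatter,
             r_random = r_random,
             necr = necr(r_true, r_scatter, r_random))
}

#' Noise-equivalent count rate
#'
#' `NECR = R_T^2 / (R_T + R_S + R_R)`: the trues rate that would give the
#' same statistical noise with no scatter or randoms. Always `<= R_T`.
#'
#' @param r_true,r_scatter,r_random Event rates (vectors allowed), counts/s.
#' @return NECR, counts/s (0 where all three rates are 0).
#' @examples
#' necr(100, 50, 50)  # 50
#' @export
necr <- function(r_true, r_scatter, r_random) {
  if (any(r_true < 0) || any(r_scatter < 0) || any(r_random < 0))
    stop("rates must be >= 0", call. = FALSE)
  tot <- r_true + r_scatter + r_random
  ifelse(tot == 0, 0, r_true^2 / tot)
}

#' Sinogram geometry template
#'
#' @param n_radial,n_angles Number of radial and angular bins.
#' @param radial_bin_mm Radial bin width, mm.
#' @param frame_duration Frame duration, s.
#' @return A `sinogram_geometry`. Radial bin centers are symmetric about 0.
#' @export
sinogram_geometry <- function(n_radial = 128, n_angles = 160,
                              radial_bin_mm = 0.8, frame_duration = 900) {
  stopifnot(n_radial > 1, n_angles > 1, radial_bin_mm > 0, frame_duration > 0)
  structure(list(n_radial = as.integer(n_radial),
                 n_angles = as.integer(n_angles),
                 radial_bin_mm = radial_bin_mm,
                 frame_duration = frame_duration),
            class = "sinogram_geometry")
}

.radial_centers <- function(geom) {
  (seq_len(geom$n_radial) - (geom$n_radial + 1) / 2) * geom$radial_bin_mm
}

#' Synthesize prompt and delayed sinograms for one frame
#'
#' Trues trace the sinusoid of the offset line source (Gaussian radial spread
#' of the source diameter); scatter forms a broad Gaussian background within
#' the phantom shadow; randoms are uniform over the phantom shadow plus the
#' NU-4 8 mm margin. Each bin is Poisson-sampled; the delayed sinogram is an
#' independent realization of the randoms expectation only.
#'
#' @param rates One row of [simulate_rates()] output (or a list with
#'   `r_true`, `r_scatter`, `r_random`).
#' @param phantom A `phantom_model` from [build_nec_phantom()].
#' @param geom A [sinogram_geometry()].
#' @param seed Optional integer seed.
#' @return List with `prompt` and `delayed` matrices
#'   (`n_radial x n_angles`), the geometry and the generating rates.
#' @export
simulate_sinograms <- function(rates, phantom, geom = sinogram_geometry(),
                               seed = NULL) {
  stopifnot(inherits(phantom, "phantom_model"), !is.null(phantom$source_offset))
  if (!is.null(seed)) set.seed(seed)
  dur <- geom$frame_duration
  s <- .radial_centers(geom)
  theta <- pi * (seq_len(geom$n_angles) - 1) / geom$n_angles
  r_ph <- phantom$phantom_radius
  # trues: line source at radius `offset` traces s = offset * cos(theta)
  trace <- phantom$source_offset * cos(theta)
  sigma_src <- if (!is.null(phantom$source_diameter))
    phantom$source_diameter / 2 else 1.6
  trues_field <- vapply(seq_along(theta), function(j) {
    w <- exp(-(s - trace[j])^2 / (2 * sigma_src^2))
    w / sum(w)
  }, numeric(length(s)))
  trues_field <- trues_field * rates$r_true * dur / geom$n_angles
  # scatter: broad, low-frequency background inside the phantom shadow
  in_shadow <- abs(s) <= r_ph
  sc <- exp(-s^2 / (2 * r_ph^2)) * in_shadow
  sc <- sc / sum(sc)
  scatter_field <- matrix(sc * rates$r_scatter * dur / geom$n_angles,
                          nrow = geom$n_radial, ncol = geom$n_angles)
  # randoms: uniform over the shadow + NU-4 margin
  in_margin <- abs(s) <= r_ph + 8
  rd <- in_margin / sum(in_margin)
  random_field <- matrix(rd * rates$r_random * dur / geom$n_angles,
                         nrow = geom$n_radial, ncol = geom$n_angles)
  lam_prompt <- trues_field + scatter_field + random_field
  prompt <- matrix(stats::rpois(length(lam_prompt), lam_prompt),
                   nrow = geom$n_radial)
  delayed <- matrix(stats::rpois(length(random_field), random_field),
                    nrow = geom$n_radial)
  list(prompt = prompt, delayed = delayed, geometry = geom, rates = rates)
}

#' NU-4-style rate extraction from a sinogram pair
#'
#' Implements the NEMA NU-4 counting procedure: bins farther than 8 mm
#' outside the phantom radius are zeroed; each angular row is circularly
#' shifted so its maximum sits at the central bin; rows are summed into one
#' radial profile; the counts inside the central +/- 7 mm band, minus the
#' linearly interpolated background spanned by the band-edge values, are the
#' trues. Randoms come from the delayed sinogram total (same mask); scatter
#' is the remainder.
#'
#' @param prompt,delayed Sinogram matrices (`n_radial x n_angles`).
#' @param geom The [sinogram_geometry()] used to create them.
#' @param phantom_radius Phantom radius, mm (default 25).
#' @param band_halfwidth,edge_margin NU-4 constants: half-width of the trues
#'   band and the mask margin outside the phantom radius, mm.
#' @return One-row data frame: `r_true`, `r_scatter`, `r_random`, `necr`.
#' @export
nu4_extract_rates <- function(prompt, delayed, geom, phantom_radius = 25,
                              band_halfwidth = 7, edge_margin = 8) {
  stopifnot(nrow(prompt) == geom$n_radial, nrow(delayed) == geom$n_radial)
  dur <- geom$frame_duration
  s <- .radial_centers(geom)
  keep <- abs(s) <= phantom_radius + edge_margin
  if (sum(keep) < 3) stop("mask leaves too few radial bins", call. = FALSE)
  prompt[!keep, ] <- 0
  delayed[!keep, ] <- 0
  n <- geom$n_radial
  ctr <- (n + 1L) %/% 2L
  shifted <- vapply(seq_len(ncol(prompt)), function(j) {
    col <- prompt[, j]
    k <- which.max(col)
    col[((seq_len(n) - 1 + (k - ctr)) %% n) + 1]
  }, numeric(n))
  profile <- rowSums(shifted)
  band <- abs(s - s[ctr]) <= band_halfwidth
  if (sum(band) < 3 || sum(band) >= sum(keep))
    stop("trues band is degenerate for this geometry", call. = FALSE)
  ib <- range(which(band))
  # linear background under the band from the values just at the band edges
  edge_lo <- profile[ib[1]]
  edge_hi <- profile[ib[2]]
  n_band <- ib[2] - ib[1] + 1L
  background <- (edge_lo + edge_hi) / 2 * n_band
  trues <- sum(profile[band]) - background
  if (trues < 0) trues <- 0
  total <- sum(profile)
  randoms <- sum(delayed)
  scatter <- total - trues - randoms
  if (scatter < 0) {
    warning("negative scatter estimate clipped to 0")
    scatter <- 0
  }
  r_t <- trues / dur; r_s <- scatter / dur; r_r <- randoms / dur
  data.frame(r_true = r_t, r_scatter = r_s, r_random = r_r,
             necr = necr(r_t, r_s, r_r))
}

#' Quadratic fit to the randoms rate
#'
#' Least-squares degree-2 polynomial `R_R(A)`; randoms grow with the square
#' of the singles rate, so the fit is forced through zero by default.
#'
#' @param activity Activities, MBq (at least 4 distinct values).
#' @param r_random Randoms rates, counts/s.
#' @param zero_intercept Force the fit through the origin (default `TRUE`).
#' @return List with `coefficients` (named `intercept`, `linear`,
#'   `quadratic`), `r_squared` (coefficient of determination about the mean)
#'   and `fitted`.
#' @export
fit_randoms_quadratic <- function(activity, r_random, zero_intercept = TRUE) {
  stopifnot(length(activity) == length(r_random))
  if (length(unique(activity)) < 4)
    stop("need at least 4 distinct activities", call. = FALSE)
  df <- data.frame(a = activity, a2 = activity^2, r = r_random)
  fit <- if (zero_intercept) stats::lm(r ~ 0 + a + a2, data = df)
  else stats::lm(r ~ a + a2, data = df)
  fitted <- stats::fitted(fit)
  ss_res <- sum((r_random - fitted)^2)
  ss_tot <- sum((r_random - mean(r_random))^2)
  cf <- stats::coef(fit)
  coefficients <- c(intercept = unname(if ("(Intercept)" %in% names(cf))
    cf[["(Intercept)"]] else 0),
    linear = unname(cf[["a"]]), quadratic = unname(cf[["a2"]]))
  list(coefficients = coefficients, r_squared = 1 - ss_res / ss_tot,
       fitted = unname(fitted))
}
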