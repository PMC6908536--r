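#' Radionuclide physical constants
#'
#' Bundle the decay constants a PET image-quality comparison needs: half-life,
#' positron branching ratio, mean/endpoint positron emission energies and any
#' prompt gammas co-emitted with the positron.
#'
#' @param name Nuclide label, e.g. `"F-18"`.
#' @param half_life Half-life in seconds.
#' @param positron_branching Positron branching ratio (fraction in \[0, 1\]).
#'   For 68Ga the *total* positron branching (0.888) is used so that count
#'   planning reproduces the published decay-equalized yields.
#' @param mean_positron_energy,max_positron_energy Mean and endpoint positron
#'   emission energies in keV (`NA` allowed for pure beta-minus emitters).
#' @param prompt_gammas Data frame with columns `energy_kev` and `yield`
#'   (fraction per decay) listing high-energy photons co-emitted with the
#'   decay; empty for pure positron emitters.
#' @param beta_minus_branching Beta-minus branching ratio (0 for pure beta-plus
#'   emitters).
#'
#' @return An object of class `radionuclide`.
#' @examples
#' f18 <- radionuclide("F-18", half_life = 109.8 * 60,
#'                     positron_branching = 0.967,
#'                     mean_positron_energy = 249.8,
#'                     max_positron_energy = 633.5)
#' decay_constant(f18$half_life)
#' @export
radionuclide <- function(name, half_life, positron_branching,
                         mean_positron_energy = NA_real_,
                         max_positron_energy = NA_real_,
                         prompt_gammas = NULL,
                         beta_minus_branching = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life) || length(half_life) != 1L || half_life <= 0)
    stop("half_life must be a single positive number of seconds", call. = FALSE)
  if (positron_branching < 0 || positron_branching > 1)
    stop("positron_branching must lie in [0, 1]", call. = FALSE)
  if (!is.na(mean_positron_energy) && mean_positron_energy <= 0)
    stop("mean_positron_energy must be positive", call. = FALSE)
  if (!is.na(max_positron_energy) && max_positron_energy <= 0)
    stop("max_positron_energy must be positive", call. = FALSE)
  if (is.null(prompt_gammas))
    prompt_gammas <- data.frame(energy_kev = numeric(0), yield = numeric(0))
  stopifnot(all(c("energy_kev", "yield") %in% names(prompt_gammas)))
  if (any(prompt_gammas$yield < 0 | prompt_gammas$yield > 1))
    stop("prompt gamma yields must lie in [0, 1]", call. = FALSE)
  if (any(prompt_gammas$energy_kev <= 0))
    stop("prompt gamma energies must be positive", call. = FALSE)
  structure(
    list(name = name,
         half_life = as.numeric(half_life),
         positron_branching = as.numeric(positron_branching),
         mean_positron_energy = as.numeric(mean_positron_energy),
         max_positron_energy = as.numeric(max_positron_energy),
         prompt_gammas = prompt_gammas,
         beta_minus_branching = as.numeric(beta_minus_branching)),
    class = "radionuclide")
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("<radionuclide> %s  T1/2 = %.4g h  BR(b+) = %.4g\n",
              x$name, x$half_life / 3600, x$positron_branching))
  if (!is.na(x$mean_positron_energy))
    cat(sprintf("  E(b+) mean/max = %.4g / %.4g keV\n",
                x$mean_positron_energy, x$max_positron_energy))
  if (nrow(x$prompt_gammas))
    cat(sprintf("  prompt gammas: %s\n",
                paste(sprintf("%.0f keV (%.1f%%)", x$prompt_gammas$energy_kev,
                              100 * x$prompt_gammas$yield), collapse = ", ")))
  invisible(x)
}

# Built-in constants: the four comparison nuclides plus the scandium
# co-products of natCa(p,x) production. Durations stored in seconds.
.nuclide_table <- function() {
  list(
    "F-18" = radionuclide("F-18", half_life = 109.8 * 60,
                          positron_branching = 0.967,
                          mean_positron_energy = 249.8,
                          max_positron_energy = 633.5),
    "Cu-64" = radionuclide("Cu-64", half_life = 12.7 * 3600,
                           positron_branching = 0.176,
                           mean_positron_energy = 278.2,
                           max_positron_energy = 653.0,
                           beta_minus_branching = 0.385),
    "Ga-68" = radionuclide("Ga-68", half_life = 67.71 * 60,
                           positron_branching = 0.888,
                           mean_positron_energy = 836.0,
                           max_positron_energy = 1890,
                           prompt_gammas = data.frame(energy_kev = 1077,
                                                      yield = 0.0322)),
    "Sc-44g" = radionuclide("Sc-44g", half_life = 3.97 * 3600,
                            positron_branching = 0.9427,
                            mean_positron_energy = 632.0,
                            max_positron_energy = 1474,
                            prompt_gammas = data.frame(energy_kev = 1157,
                                                       yield = 0.999)),
    "Sc-43" = radionuclide("Sc-43", half_life = 3.89 * 3600,
                           positron_branching = 0.881,
                           mean_positron_energy = 508,
                           max_positron_energy = 1199),
    "Sc-44m" = radionuclide("Sc-44m", half_life = 58.61 * 3600,
                            positron_branching = 0),
    "Sc-47" = radionuclide("Sc-47", half_life = 3.35 * 86400,
                           positron_branching = 0,
                           beta_minus_branching = 1),
    "Sc-48" = radionuclide("Sc-48", half_life = 43.67 * 3600,
                           positron_branching = 0,
                           beta_minus_branching = 1))
}

#' Look up a built-in radionuclide
#'
#' The package ships constants for the four comparison nuclides (18F, 64Cu,
#' 68Ga, 44gSc) and the scandium isotopes co-produced when irradiating natural
#' calcium. Constants can be overridden by constructing a [radionuclide()]
#' directly.
#'
#' @param name One of `"F-18"`, `"Cu-64"`, `"Ga-68"`, `"Sc-44g"`, `"Sc-43"`,
#'   `"Sc-44m"`, `"Sc-47"`, `"Sc-48"` (case-insensitive; `"18F"` style aliases
#'   accepted).
#' @return A `radionuclide` object.
#' @examples
#' get_nuclide("Ga-68")$positron_branching
#' @export
get_nuclide <- function(name) {
  tab <- .nuclide_table()
  key <- toupper(gsub("[^A-Za-z0-9]", "", name))
  keys <- toupper(gsub("[^A-Za-z0-9]", "", names(tab)))
  # also accept "18F" ordering
  flip <- vapply(names(tab), function(n) {
    p <- strsplit(n, "-", fixed = TRUE)[[1]]
    toupper(paste0(p[2], p[1]))
  }, character(1))
  i <- match(key, keys)
  if (is.na(i)) i <- match(key, flip)
  if (is.na(i))
    stop(sprintf("unknown nuclide '%s'; see ?get_nuclide", name), call. = FALSE)
  tab[[i]]
}

#' List built-in nuclide names
#' @return Character vector of nuclide labels understood by [get_nuclide()].
#' @export
list_nuclides <- function() names(.nuclide_table())

#' Radioactive decay constant
#'
#' @param half_life Half-life in seconds.
#' @return Decay constant lambda = ln(2) / half-life, per second.
#' @examples
#' decay_constant(log(2))      # 1 /s
#' decay_constant(109.8 * 60)  # 18F
#' @export
decay_constant <- function(half_life) {
  if (any(!is.finite(half_life)) || any(half_life <= 0))
    stop("half_life must be positive", call. = FALSE)
  log(2) / half_life
}

.as_nuclide <- function(nuclide) {
  if (is.character(nuclide)) get_nuclide(nuclide) else nuclide
}

#' Cumulative positron annihilations over an acquisition
#'
#' Number of positron decays from a source of initial activity `start_activity`
#' over `duration` seconds: N = A0 * BR * (1 - exp(-lambda t)) / lambda. Each
#' positron decay yields one annihilation photon pair, so this is the count
#' budget available to the scanner.
#'
#' @param start_activity Activity at acquisition start, Bq.
#' @param nuclide A [radionuclide()] or a name accepted by [get_nuclide()].
#' @param duration Acquisition duration, seconds.
#' @return Expected number of positron decays (annihilations).
#' @examples
#' positron_decays(3.7e6, "F-18", 1200)   # ~4.03e9
#' positron_decays(3.7e6, "Cu-64", 1200)  # ~0.774e9
#' @export
positron_decays <- function(start_activity, nuclide, duration) {
  nuclide <- .as_nuclide(nuclide)
  if (any(start_activity < 0)) stop("start_activity must be >= 0", call. = FALSE)
  if (any(duration < 0)) stop("duration must be >= 0", call. = FALSE)
  lam <- decay_constant(nuclide$half_life)
  start_activity * nuclide$positron_branching * (1 - exp(-lam * duration)) / lam
}

#' Acquisition time matching a target positron yield
#'
#' Closed-form inverse of [positron_decays()]:
#' t = -(1/lambda) * log(1 - N * lambda / (A0 * BR)). Used to plan
#' decay-equalized acquisitions in which every nuclide contributes the same
#' number of annihilations as a reference 18F scan.
#'
#' @inheritParams positron_decays
#' @param target_decays Required number of positron decays.
#' @return Acquisition duration in seconds.
#' @examples
#' n_ref <- positron_decays(3.7e6, "F-18", 1200)
#' equalized_acquisition_time("Ga-68", 3.7e6, n_ref)
#' @export
equalized_acquisition_time <- function(nuclide, start_activity, target_decays) {
  nuclide <- .as_nuclide(nuclide)
  if (target_decays < 0) stop("target_decays must be >= 0", call. = FALSE)
  if (start_activity <= 0) stop("start_activity must be > 0", call. = FALSE)
  if (nuclide$positron_branching <= 0)
    stop("nuclide has zero positron branching", call. = FALSE)
  lam <- decay_constant(nuclide$half_life)
  nmax <- start_activity * nuclide$positron_branching / lam
  if (target_decays >= nmax)
    stop(sprintf(
      "target of %.3g decays is infeasible: asymptotic maximum for %s at %.3g Bq is %.3g",
      target_decays, nuclide$name, start_activity, nmax), call. = FALSE)
  -log(1 - target_decays * lam / (start_activity * nuclide$positron_branching)) / lam
}

#' Activity ratio giving equal instantaneous positron emission rates
#'
#' How much activity of nuclide `a` is needed per unit activity of nuclide `b`
#' for the two sources to emit positrons at the same rate; this is simply the
#' ratio of positron branching ratios BR(b)/BR(a). E.g. 64Cu requires about
#' 5.5 times the activity of 18F.
#'
#' @param a,b [radionuclide()] objects or names.
#' @return Dimensionless activity ratio.
#' @examples
#' activity_ratio_for_equal_positron_rate("Cu-64", "F-18")  # ~5.5
#' @export
activity_ratio_for_equal_positron_rate <- function(a, b) {
  a <- .as_nuclide(a); b <- .as_nuclide(b)
  if (a$positron_branching <= 0 || b$positron_branching <= 0)
    stop("both nuclides need positive positron branching", call. = FALSE)
  b$positron_branching / a$positron_branching
}

#' Time for a source to decay between two activities
#'
#' @param nuclide A [radionuclide()] or name.
#' @param activity_start,activity_end Activities in any common unit, with
#'   `0 < activity_end <= activity_start`.
#' @return Decay time in seconds: T1/2 * log2(A_start / A_end).
#' @examples
#' decay_time("Cu-64", 100, 1.5) / 86400  # ~3.2 days
#' @export
decay_time <- function(nuclide, activity_start, activity_end) {
  nuclide <- .as_nuclide(nuclide)
  if (activity_end <= 0 || activity_start <= 0)
    stop("activities must be positive", call. = FALSE)
  if (activity_end > activity_start)
    stop("activity_end must not exceed activity_start", call. = FALSE)
  nuclide$half_life * log2(activity_start / activity_end)
}

#' Decay-equalized acquisition plan
#'
#' @param nuclide A [radionuclide()] or name.
#' @param start_activity Activity at acquisition start, Bq.
#' @param duration Acquisition duration, s.
#' @return An `acquisition_plan` with the expected positron decay count.
#' @examples
#' acquisition_plan("Sc-44g", 3.7e6, 1190)
#' @export
acquisition_plan <- function(nuclide, start_activity, duration) {
  nuclide <- .as_nuclide(nuclide)
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  structure(
    list(nuclide = nuclide,
         start_activity = start_activity,
         duration = duration,
         expected_positron_decays =
           positron_decays(start_activity, nuclide, duration)),
    class = "acquisition_plan")
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat(sprintf("<acquisition_plan> %s: %.3g Bq for %.0f s -> %.3g positron decays\n",
              x$nuclide$name, x$start_activity, x$duration,
              x$expected_positron_decays))
  invisible(x)
}

#' Decay-equalized acquisition-time table
#'
#' Reproduces the standard planning table: for each nuclide, the positron
#' annihilations accumulated in the reference conditions (3.7 MBq over 1200 s
#' by default) and the time that nuclide needs, at the same starting activity,
#' to match the reference nuclide's yield.
#'
#' @param nuclides Character vector of nuclide names (or list of
#'   [radionuclide()] objects).
#' @param reference Name of the reference nuclide (default `"F-18"`).
#' @param start_activity Common starting activity, Bq.
#' @param reference_duration Reference acquisition duration, s.
#' @param round_reference If `TRUE` (default), the reference yield is rounded
#'   to 3 significant figures — the precision at which planning tables print
#'   it — before inverting for the other nuclides' times.
#' @return Data frame with columns `nuclide`, `positron_annihilations`
#'   (over `reference_duration`) and `equalized_time_s`.
#' @examples
#' equalized_time_table(c("F-18", "Ga-68", "Cu-64", "Sc-44g"))
#' @export
equalized_time_table <- function(nuclides = c("F-18", "Ga-68", "Cu-64", "Sc-44g"),
                                 reference = "F-18",
                                 start_activity = 3.7e6,
                                 reference_duration = 1200,
                                 round_reference = TRUE) {
  nucs <- lapply(nuclides, .as_nuclide)
  ref <- .as_nuclide(reference)
  n_ref <- positron_decays(start_activity, ref, reference_duration)
  target <- if (round_reference) signif(n_ref, 3) else n_ref
  ann <- vapply(nucs, function(n)
    positron_decays(start_activity, n, reference_duration), numeric(1))
  tms <- vapply(nucs, function(n)
    equalized_acquisition_time(n, start_activity, target), numeric(1))
  data.frame(nuclide = vapply(nucs, `[[`, character(1), "name"),
             positron_annihilations = ann,
             equalized_time_s = tms)
}
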