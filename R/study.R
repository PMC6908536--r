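# End-to-end study orchestration: plan -> simulate -> analyze -> report,
# mirroring the three phantom studies (image quality, Derenzo contrast,
# count rates) on synthetic data.

.study_report <- function(study, tables, orderings, seed, config) {
  structure(list(study = study, tables = tables, orderings = orderings,
                 seed = seed, config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %s (seed %s)\n", x$study,
              if (is.null(x$seed)) "none" else x$seed))
  for (nm in names(x$tables)) {
    cat("--", nm, "--\n")
    print(x$tables[[nm]], row.names = FALSE, digits = 4)
  }
  if (!is.null(x$orderings) && nrow(x$orderings)) {
    cat("-- orderings --\n")
    print(x$orderings, row.names = FALSE)
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' One directory per study: `config.yaml`, one CSV per table, `report.json`.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(report$config, file.path(dir, "config.yaml"))
  for (nm in names(report$tables))
    utils::write.csv(report$tables[[nm]],
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  jsonlite::write_json(
    list(study = report$study, seed = report$seed,
         tables = report$tables, orderings = report$orderings),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}

.ord_row <- function(label, ok)
  data.frame(check = label, pass = ok)

#' Image-quality comparison study
#'
#' For each nuclide: a decay-equalized acquisition plan (same positron yield
#' as the 18F reference), a simulated IQ-phantom image, then %SD, recovery
#' coefficients and spill-over ratios. The report carries the expected
#' qualitative rankings (long-range positron emitters spill more into the
#' water insert and recover less in small rods) as pass/fail checks.
#'
#' @param nuclides Nuclide names (default the four comparison nuclides).
#' @param seed Base seed; realization i uses `seed + i - 1` per nuclide.
#' @param spacing Simulation grid spacing, mm (default 0.2).
#' @param start_activity Starting activity, Bq (default 3.7 MBq).
#' @param reference_duration 18F reference acquisition, s (default 1200).
#' @param config A [degradation_config()].
#' @param system_fwhm System/reconstruction blur FWHM, mm.
#' @param phantom An IQ `phantom_model` (default [build_iq_phantom()]).
#' @param supersample Rasterization supersampling.
#' @return A `study_report` with tables `plan` and `metrics`.
#' @export
run_iq_study <- function(nuclides = c("F-18", "Cu-64", "Ga-68", "Sc-44g"),
                         seed = 1, spacing = 0.2,
                         start_activity = 3.7e6, reference_duration = 1200,
                         config = degradation_config(),
                         system_fwhm = 1.5,
                         phantom = build_iq_phantom(),
                         supersample = 3) {
  plan_tab <- equalized_time_table(nuclides, start_activity = start_activity,
                                   reference_duration = reference_duration)
  grid <- grid_for_phantom(phantom, spacing = spacing)
  vox <- voxelize(phantom, grid, supersample = supersample)
  uvoi <- cylindrical_voi(c(0, 0, phantom$uniform_center),
                          0.75 * phantom$active_diameter, 10)
  rows <- list()
  for (i in seq_along(nuclides)) {
    nm <- plan_tab$nuclide[i]
    plan <- acquisition_plan(nuclides[i], start_activity,
                             plan_tab$equalized_time_s[i])
    img <- simulate_recon_image(vox, nuclides[i], plan, config = config,
                                system_fwhm = system_fwhm,
                                seed = if (is.null(seed)) NULL else seed + i - 1)
    rows[[nm]] <- iq_metrics(img, phantom, uniform_voi = uvoi, nuclide = nm)
  }
  metrics <- do.call(rbind, rows)
  row.names(metrics) <- NULL
  val <- function(nuc, met) metrics$value[metrics$nuclide == nuc &
                                            metrics$metric == met]
  ords <- NULL
  if (all(c("F-18", "Cu-64", "Ga-68", "Sc-44g") %in% metrics$nuclide)) {
    ords <- rbind(
      .ord_row("SOR water: Ga-68 > Sc-44g > max(F-18, Cu-64)",
               val("Ga-68", "sor_water") > val("Sc-44g", "sor_water") &&
                 val("Sc-44g", "sor_water") > max(val("F-18", "sor_water"),
                                                  val("Cu-64", "sor_water"))),
      .ord_row("RC 5 mm: min(F-18, Cu-64) > Sc-44g > Ga-68",
               min(val("F-18", "rc_5mm"), val("Cu-64", "rc_5mm")) >
                 val("Sc-44g", "rc_5mm") &&
                 val("Sc-44g", "rc_5mm") > val("Ga-68", "rc_5mm")))
  }
  .study_report("iq", list(plan = plan_tab, metrics = metrics), ords, seed,
                list(study = "iq", nuclides = nuclides, spacing = spacing,
                     start_activity = start_activity,
                     reference_duration = reference_duration,
                     system_fwhm = system_fwhm,
                     scatter_fraction = config$scatter_fraction,
                     scatter_corrected = config$scatter_corrected,
                     seed = seed))
}

#' All NEMA IQ metrics for one image
#'
#' @param image A `recon_image` of the IQ phantom.
#' @param phantom The `phantom_model` from [build_iq_phantom()].
#' @param uniform_voi Uniformity VOI; default 75% of the active diameter,
#'   10 mm long, centered in the uniform section.
#' @param nuclide Label carried into the output.
#' @return Long-format data frame `(nuclide, metric, value, sigma)` with one
#'   row for %SD, one per rod RC, and one per cold-insert SOR.
#' @export
iq_metrics <- function(image, phantom, uniform_voi = NULL, nuclide = NA) {
  if (is.null(uniform_voi))
    uniform_voi <- cylindrical_voi(c(0, 0, phantom$uniform_center),
                                   0.75 * phantom$active_diameter, 10)
  uni <- voi_statistics(image, uniform_voi)
  rc <- recovery_coefficients(image, phantom$rods, uni,
                              axial_center = phantom$rod_section_center)
  sors <- lapply(seq_len(nrow(phantom$inserts)), function(i) {
    ins <- phantom$inserts[i, ]
    spill_over_ratio(image,
                     cylindrical_voi(c(ins$x, ins$y, ins$z),
                                     ins$diameter / 2, 7.5),
                     uni, region = ins$region)
  })
  sors <- do.call(rbind, sors)
  data.frame(
    nuclide = nuclide,
    metric = c("pct_sd",
               sprintf("rc_%gmm", rc$rod_diameter),
               paste0("sor_", sors$region)),
    value = c(uni$pct_sd, rc$rc, sors$sor),
    sigma = c(NA, rc$sigma_rc, sors$sigma_sor))
}

#' Derenzo contrast study
#'
#' Simulates the Derenzo phantom for each nuclide at a fixed coincidence
#' budget and extracts the contrast-versus-rod-size curve. The default grid
#' is a single transverse slab: the rods are axially invariant over scales
#' much longer than the blur kernels, so the slab is the axial projection of
#' the rod region and the full coincidence budget contributes to it.
#'
#' @param nuclides Nuclide names.
#' @param budget Total coincidence budget (default 5e7; budgets below 1e6
#'   trigger a warning).
#' @param seed Base seed (per-nuclide offset as in [run_iq_study()]).
#' @param spacing Grid spacing, mm.
#' @param config A [degradation_config()].
#' @param system_fwhm System blur FWHM, mm.
#' @param phantom A `phantom_model` from [build_derenzo()].
#' @param slab Use a single-slice grid (default `TRUE`).
#' @return A `study_report` with table `contrast` and the 2.5 mm ordering
#'   check.
#' @export
run_derenzo_study <- function(nuclides = c("F-18", "Cu-64", "Ga-68", "Sc-44g"),
                              budget = 5e7, seed = 1, spacing = 0.2,
                              config = degradation_config(),
                              system_fwhm = 1.5,
                              phantom = build_derenzo(), slab = TRUE) {
  if (budget < 1e6)
    warning("coincidence budget below 1e6; contrast will be noise-limited")
  grid <- grid_for_phantom(phantom, spacing = spacing,
                           nz = if (slab) 1 else NULL)
  vox <- voxelize(phantom, grid)
  decays <- budget / config$detection_efficiency
  rows <- list()
  for (i in seq_along(nuclides)) {
    nm <- .as_nuclide(nuclides[i])$name
    img <- simulate_recon_image(vox, nuclides[i], decays, config = config,
                                system_fwhm = system_fwhm,
                                seed = if (is.null(seed)) NULL else seed + i - 1)
    cc <- contrast_curve(img, phantom)
    cc$nuclide <- nm
    rows[[nm]] <- cc
  }
  tab <- do.call(rbind, rows)
  row.names(tab) <- NULL
  val <- function(nuc) tab$contrast[tab$nuclide == nuc &
                                      tab$rod_diameter == 2.5]
  ords <- NULL
  if (all(c("F-18", "Cu-64", "Ga-68", "Sc-44g") %in% tab$nuclide))
    ords <- .ord_row("contrast 2.5 mm: F-18 >= Cu-64 > Sc-44g > Ga-68",
                     val("F-18") >= val("Cu-64") &&
                       val("Cu-64") > val("Sc-44g") &&
                       val("Sc-44g") > val("Ga-68"))
  .study_report("derenzo", list(contrast = tab), ords, seed,
                list(study = "derenzo", nuclides = nuclides, budget = budget,
                     spacing = spacing, system_fwhm = system_fwhm,
                     slab = slab, seed = seed))
}

#' Count-rate (NEC) study
#'
#' For each nuclide: a decaying-source frame schedule (quarter-half-life
#' rule), synthetic prompt/delayed sinograms per frame, NU-4 rate extraction,
#' the NECR curve and the quadratic randoms fit over activities up to
#' 100 MBq. 64Cu is excluded by default: its low positron branching would
#' require ~5.5 times the 18F activity for the same positron rate and more
#' than 3 days to decay from 100 to 1.5 MBq.
#'
#' @param nuclides Nuclide names (default 18F, 68Ga, 44gSc).
#' @param start_activity,stop_activity Framing range, MBq.
#' @param params A [rate_model_params()].
#' @param seed Base seed.
#' @param phantom A `phantom_model` from [build_nec_phantom()].
#' @param geom A [sinogram_geometry()] template (frame duration is taken
#'   from the schedule).
#' @return A `study_report` with tables `rates` (extracted per frame) and
#'   `randoms_fit` (quadratic-fit R^2 per nuclide).
#' @export
run_nec_study <- function(nuclides = c("F-18", "Ga-68", "Sc-44g"),
                          start_activity = 100, stop_activity = 1.5,
                          params = rate_model_params(), seed = 1,
                          phantom = build_nec_phantom(),
                          geom = sinogram_geometry()) {
  dropped <- vapply(nuclides, function(n) .as_nuclide(n)$name, character(1))
  if ("Cu-64" %in% dropped)
    message("Cu-64 excluded from the count-rate study: ",
            "low positron branching and long half-life make the ",
            "decay-equalized acquisition impractically long")
  nuclides <- nuclides[dropped != "Cu-64"]
  all_rates <- list()
  fits <- list()
  for (i in seq_along(nuclides)) {
    nuc <- .as_nuclide(nuclides[i])
    frames <- frame_schedule(nuc, start_activity, stop_activity)
    truth <- simulate_rates(nuc, frames = frames, params = params)
    g <- geom
    g$frame_duration <- frames$t_end[1] - frames$t_start[1]
    ext <- lapply(seq_len(nrow(frames)), function(k) {
      sg <- simulate_sinograms(truth[k, ], phantom, g,
                               seed = if (is.null(seed)) NULL
                               else seed + 1000 * i + k)
      nu4_extract_rates(sg$prompt, sg$delayed, g,
                        phantom_radius = phantom$phantom_radius)
    })
    ext <- do.call(rbind, ext)
    ext <- cbind(nuclide = nuc$name, activity = frames$activity, ext)
    all_rates[[nuc$name]] <- ext
    sel <- ext$activity <= 100
    fit <- fit_randoms_quadratic(ext$activity[sel], ext$r_random[sel])
    fits[[nuc$name]] <- data.frame(nuclide = nuc$name,
                                   r_squared = fit$r_squared,
                                   quadratic = fit$coefficients[["quadratic"]],
                                   linear = fit$coefficients[["linear"]])
  }
  rates <- do.call(rbind, all_rates)
  row.names(rates) <- NULL
  fits <- do.call(rbind, fits)
  row.names(fits) <- NULL
  ords <- .ord_row("randoms quadratic fit R^2 >= 0.999 for every nuclide",
                   all(fits$r_squared >= 0.999))
  .study_report("nec", list(rates = rates, randoms_fit = fits), ords, seed,
                list(study = "nec", nuclides = nuclides,
                     start_activity = start_activity,
                     stop_activity = stop_activity, seed = seed))
}
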