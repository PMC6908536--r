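# YAML interchange for nuclide constants and phantom specifications, so a
# study can be driven from plain-text configuration files.

#' Write a nuclide library to YAML
#'
#' @param nuclides List of [radionuclide()] objects (default: the built-in
#'   library).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_nuclide_library <- function(nuclides = lapply(list_nuclides(), get_nuclide),
                                  path) {
  entries <- lapply(nuclides, function(n) {
    e <- list(half_life_s = n$half_life,
              positron_branching = n$positron_branching,
              beta_minus_branching = n$beta_minus_branching)
    if (!is.na(n$mean_positron_energy)) {
      e$mean_positron_energy_kev <- n$mean_positron_energy
      e$max_positron_energy_kev <- n$max_positron_energy
    }
    if (nrow(n$prompt_gammas))
      e$prompt_gammas <- lapply(seq_len(nrow(n$prompt_gammas)), function(i)
        list(energy_kev = n$prompt_gammas$energy_kev[i],
             yield = n$prompt_gammas$yield[i]))
    e
  })
  names(entries) <- vapply(nuclides, `[[`, character(1), "name")
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Read a nuclide library from YAML
#'
#' The file maps nuclide names to the [radionuclide()] fields as written by
#' [write_nuclide_library()]; entries override or extend the built-in
#' constants for any function taking a `radionuclide`.
#'
#' @param path YAML path.
#' @return Named list of [radionuclide()] objects.
#' @export
read_nuclide_library <- function(path) {
  entries <- yaml::read_yaml(path)
  out <- lapply(names(entries), function(nm) {
    e <- entries[[nm]]
    pg <- NULL
    if (!is.null(e$prompt_gammas))
      pg <- data.frame(
        energy_kev = vapply(e$prompt_gammas, `[[`, numeric(1), "energy_kev"),
        yield = vapply(e$prompt_gammas, `[[`, numeric(1), "yield"))
    radionuclide(nm, e$half_life_s, e$positron_branching,
                 mean_positron_energy = e$mean_positron_energy_kev %||% NA_real_,
                 max_positron_energy = e$max_positron_energy_kev %||% NA_real_,
                 prompt_gammas = pg,
                 beta_minus_branching = e$beta_minus_branching %||% 0)
  })
  names(out) <- names(entries)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a phantom from a configuration list or YAML file
#'
#' The configuration holds a `type` (`"iq"`, `"derenzo"` or `"nec"`) plus any
#' arguments of the corresponding builder ([build_iq_phantom()],
#' [build_derenzo()], [build_nec_phantom()]).
#'
#' @param config A list, or the path of a YAML file containing one.
#' @return A `phantom_model`.
#' @examples
#' phantom_from_config(list(type = "derenzo", diameters = c(2.5, 2, 1.5)))
#' @export
phantom_from_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$type))
  builder <- switch(config$type,
                    iq = build_iq_phantom,
                    derenzo = build_derenzo,
                    nec = build_nec_phantom,
                    stop(sprintf("unknown phantom type '%s'", config$type),
                         call. = FALSE))
  args <- config[setdiff(names(config), "type")]
  args <- lapply(args, function(a) if (is.list(a)) unlist(a) else a)
  do.call(builder, args)
}
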