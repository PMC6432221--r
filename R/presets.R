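#' Polymer parameter presets
#'
#' Persistence length and monomer size (in nm) for the standard set of
#' synthetic polymers, polyelectrolytes at high salt and biofilaments used
#' throughout: polyethylene (PE, in dodecanol), polyisobutylene (PIB, in
#' benzene), atactic polystyrene (PS, in cyclohexane),
#' polydimethylsiloxane (PDMS, in hexane), NaPSS and PDADMAC at high salt,
#' hyaluronan (HA; the literature reports two persistence-length ranges,
#' kept as two rows with the range midpoints), duplex DNA, intermediate
#' filament vimentin (IF) and F-actin. The printed aspect ratio
#' `ell/b` is carried along for cross-checking; the recomputed ratio
#' agrees within rounding.
#'
#' @return A tibble with columns `name`, `ell` (nm), `b` (nm),
#'   `ratio_printed`.
#' @export
polymer_presets <- function() {
  tibble(
    name = c("PE", "PIB", "PS", "PDMS", "NaPSS", "PDADMAC",
             "HA (low)", "HA (high)", "d-DNA", "IF", "F-actin"),
    ell = c(0.59, 0.59, 0.86, 0.57, 1.0, 3.0, 4.5, 8.5, 50, 1e3, 17e3),
    b = c(0.13, 0.26, 0.26, 0.29, 0.25, 0.47, 1.0, 1.0, 0.34, 10, 5),
    ratio_printed = c(4.5, 2.3, 3.3, 2, 4, 5.3, 4.5, 8.5, 150, 100, 3400)
  )
}

#' Chemisorption length-scale table
#'
#' Applies [chemisorption_scales()] to every preset: the zipping-loop size
#' `s0 = (ell b^2)^(1/3)` and the multiple-nucleation length
#' `S* = ell^(5/3) b^(-2/3)`, in nm.
#'
#' @param presets A preset tibble; defaults to [polymer_presets()].
#' @return A tibble with columns `name`, `ell`, `b`, `s0`, `S_star`.
#' @export
chemisorption_table <- function(presets = polymer_presets()) {
  dplyr::bind_cols(presets["name"],
                   chemisorption_scales(presets$ell, presets$b))
}

# ---------------------------------------------------------------------------
# Run configuration (YAML)

#' Run configuration objects
#'
#' A small container for reproducible runs: module name, parameter map,
#' seed and output paths. Serialises to YAML and round-trips losslessly.
#'
#' @param module Module name (character scalar).
#' @param params Named list of parameters.
#' @param seed Integer seed.
#' @param out Named list or character vector of output paths.
#' @return An object of class `run_config`.
#' @export
run_config <- function(module, params = list(), seed = 1L, out = list()) {
  if (!is.character(module) || length(module) != 1) {
    abort("`module` must be a character scalar.")
  }
  if (!is.list(params) || (length(params) && is.null(names(params)))) {
    abort("`params` must be a named list.")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) abort("`seed` must be an integer.")
  structure(list(module = module, params = params, seed = seed,
                 out = as.list(out)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (field in c("module", "seed")) {
    if (is.null(raw[[field]])) abort(sprintf("config is missing `%s`.", field))
  }
  run_config(raw$module, as.list(raw$params), raw$seed, as.list(raw$out))
}
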