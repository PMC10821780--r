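#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON-compatible YAML) run configuration, rejects unknown
#' keys, applies defaults, and resolves named hardware presets. A seed is
#' mandatory: runs must be reproducible by construction.
#'
#' Recognized top-level keys: `schema_version`, `seed`, `technique`
#' (`dcs`/`scos`), `detector` (preset name or field list), `laser` (preset
#' name or field list), `fiber` (preset name or field list), `strategy`,
#' `sds_mm`, `fit_fraction`, `t_exp`, `s_over_p`, `sample_rate`,
#' `n_realizations`, `geometry` (list: `depth_mm`, `n_photons`,
#' `wavelength_nm`), `sweep_preset`, `out_dir`.
#'
#' @param path Path to the configuration file.
#' @return An object of class `run_config`: the validated, fully resolved
#'   configuration list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("schema_version", "seed", "technique", "detector", "laser",
             "fiber", "strategy", "sds_mm", "fit_fraction", "t_exp",
             "s_over_p", "sample_rate", "n_realizations", "geometry",
             "sweep_preset", "out_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(raw$seed)) stop("config must declare an explicit integer seed")
  if (!is.numeric(raw$seed) || raw$seed != round(raw$seed)) {
    stop("config key 'seed': must be an integer")
  }
  defaults <- list(schema_version = 1, technique = "dcs",
                   strategy = "cw_single", sds_mm = 25, fit_fraction = 1,
                   sample_rate = 10, n_realizations = 100,
                   geometry = list(), out_dir = ".")
  cfg <- utils::modifyList(defaults, raw)
  if (!cfg$technique %in% c("dcs", "scos")) {
    stop("config key 'technique': must be 'dcs' or 'scos'")
  }
  geo_defaults <- list(depth_mm = 15, n_photons = 1e6, wavelength_nm = NULL)
  unknown_geo <- setdiff(names(cfg$geometry), names(geo_defaults))
  if (length(unknown_geo) > 0) {
    stop("unknown geometry key(s): ", paste(unknown_geo, collapse = ", "))
  }
  cfg$geometry <- utils::modifyList(geo_defaults, cfg$geometry)

  cfg$detector <- resolve_preset(cfg$detector, detector_preset, detector_model,
                                 if (cfg$technique == "dcs") "dcs_850_sispad"
                                 else "scos_850_cmos", "detector")
  cfg$laser <- resolve_preset(cfg$laser, laser_preset, laser_model,
                              "laser_850", "laser")
  cfg$fiber <- resolve_preset(cfg$fiber, fiber_preset, fiber_model,
                              if (cfg$technique == "dcs") "smf_780hp"
                              else "bundle_scos", "fiber")
  if (is.null(cfg$geometry$wavelength_nm)) {
    cfg$geometry$wavelength_nm <- cfg$laser$wavelength_nm
  }
  if (cfg$technique == "scos" && is.null(cfg$t_exp)) cfg$t_exp <- 6.67e-3
  if (cfg$technique == "scos" && is.null(cfg$s_over_p)) cfg$s_over_p <- 1
  structure(cfg, class = "run_config")
}

resolve_preset <- function(x, preset_fn, model_fn, default_name, what) {
  if (is.null(x)) return(preset_fn(default_name))
  if (is.character(x) && length(x) == 1) return(preset_fn(x))
  if (is.list(x)) return(do.call(model_fn, x))
  stop("config key '", what, "': expected a preset name or a field list")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  cat(sprintf("  technique: %s, seed: %d, strategy: %s\n",
              x$technique, as.integer(x$seed), x$strategy))
  cat(sprintf("  detector: %s | laser: %s | fiber: %s\n",
              x$detector$name, x$laser$name, x$fiber$name))
  cat(sprintf("  sds_mm: %s, sample_rate: %g Hz, n_realizations: %d\n",
              paste(x$sds_mm, collapse = ","), x$sample_rate,
              x$n_realizations))
  invisible(x)
}

#' Write a provenance block for a run
#'
#' Serializes the resolved configuration, seed, package version and input file
#' hashes next to the outputs, so any result can be traced to its inputs.
#'
#' @param config A `run_config` (or any list).
#' @param out_dir Output directory.
#' @param inputs Character vector of input file paths to hash.
#' @return The provenance file path, invisibly.
#' @export
write_provenance <- function(config, out_dir, inputs = character(0)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hashes <- vapply(inputs, function(p) {
    if (file.exists(p)) as.character(tools::md5sum(p)) else NA_character_
  }, character(1))
  prov <- list(
    package_version = as.character(utils::packageVersion("speckleflow")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass_deep(config),
    input_hashes = as.list(hashes)
  )
  path <- file.path(out_dir, "provenance.yaml")
  yaml::write_yaml(prov, path)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
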