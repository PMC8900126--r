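#' Default run configuration
#'
#' One serializable record of every tunable default: global seed, physical
#' parameters of the screened-electrostatics surrogate, coarse-grained
#' geometry, clustering cutoffs and mass bookkeeping. Written beside primary
#' outputs so a run can be regenerated from its sidecar alone.
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @param ... overrides of any default field.
#' @return list of class `run_config`.
#' @export
default_config <- function(seed = 1, out_dir = ".", ...) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    eps_r = 80,
    ionic_strength_M = 0.1,
    temperature_K = 298,
    grid_spacing_nm = 0.2,
    hotspot_threshold_mV = -10,
    hotspot_min_voxels = 5,
    zn_min_separation_nm = 0.4,
    bond_length_nm = 0.515,
    charge_offset_nm = 0.35,
    alkyl_offset_nm = 0.55,
    persistence_length_nm = 5,
    alkyl_cutoff_nm = 0.6,
    acid_cutoff_nm = 0.8,
    contact_distance_nm = 0.3,
    proximity_range_A = c(10, 15),
    ds_cm = 0.9,
    amide_fraction = 200 / 900,
    mass_convention = "sodium_salt",
    log_level = "info"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Write the effective configuration beside an output
#'
#' @param cfg a `run_config`.
#' @param path the primary output path; the config lands at
#'   `<path>.config.json`.
#' @return the sidecar path, invisibly.
#' @export
write_config_sidecar <- function(cfg, path) {
  side <- paste0(path, ".config.json")
  jsonlite::write_json(unclass(cfg), side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' @rdname write_config_sidecar
#' @param path path of a `.config.json` sidecar.
#' @export
read_config_sidecar <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, cfg)
}
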