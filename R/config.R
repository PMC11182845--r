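#' Pipeline configuration
#'
#' Holds the distance and binning constants of the analysis. Defaults are the
#' field's working values: tau within 3 um of a vessel mask is "surface" tau,
#' segments are 10 um along-vessel intervals, object densities use a 30 um
#' shell, voxel export stops at 100 um, radial profiles step at 1 um, and
#' segments are ranked into deciles.
#'
#' @param surface_window_um distance defining the vessel surface (um).
#' @param bin_length_um along-vessel bin length (um).
#' @param shell_max_um object-density shell radius (um).
#' @param export_max_um voxel export radius (um).
#' @param profile_step_um radial profile step (um).
#' @param n_percentile_groups number of percentile groups (10 = deciles).
#' @param coloc_radius_um neuron-NFT colocalization radius (um).
#' @param rng_seed integer seed recorded in manifests.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(surface_window_um = 3, bin_length_um = 10,
                            shell_max_um = 30, export_max_um = 100,
                            profile_step_um = 1, n_percentile_groups = 10,
                            coloc_radius_um = 5, rng_seed = 1L) {
  cfg <- list(surface_window_um = surface_window_um,
              bin_length_um = bin_length_um,
              shell_max_um = shell_max_um,
              export_max_um = export_max_um,
              profile_step_um = profile_step_um,
              n_percentile_groups = as.integer(n_percentile_groups),
              coloc_radius_um = coloc_radius_um,
              rng_seed = as.integer(rng_seed))
  if (!(cfg$surface_window_um > 0 && cfg$surface_window_um <= cfg$shell_max_um &&
        cfg$shell_max_um <= cfg$export_max_um))
    stop("need 0 < surface_window_um <= shell_max_um <= export_max_um")
  if (cfg$bin_length_um <= 0) stop("bin_length_um must be > 0")
  if (cfg$n_percentile_groups < 2) stop("n_percentile_groups must be >= 2")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from JSON
#' @param path JSON file whose fields override [pipeline_config()] defaults.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, raw[intersect(names(raw), known)])
}

#' Write a run manifest
#'
#' Records the configuration, seed, and MD5 hashes of the input files so a
#' deterministic stage can be reproduced and audited.
#'
#' @param path output JSON path.
#' @param config a `pipeline_config` (or any list of parameters).
#' @param inputs character vector of input file paths (hashed).
#' @param extra optional named list appended verbatim.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(), extra = list()) {
  inputs <- inputs[file.exists(inputs)]
  man <- c(list(config = unclass(config),
                seed = config$rng_seed,
                inputs = as.list(tools::md5sum(inputs)),
                timestamp = format(Sys.time(), tz = "UTC")),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
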