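# Pipeline configuration: every threshold in one place, resolved and
# written next to each run's outputs.

#' Pipeline configuration
#'
#' Collects all tunable parameters of the pipeline with their shipped
#' defaults; any can be overridden by name.  Every command-line entry point
#' writes the fully resolved configuration as JSON next to its outputs.
#'
#' @param ... name-value overrides, e.g. `patch_radius = 8`.
#' @return named list of class `vhh_config`.
#' @examples
#' vhh_config(hotspot_distance = 5)$hotspot_distance
#' @export
vhh_config <- function(...) {
  cfg <- list(
    patch_radius = 10,          # A, solubility structural correction
    hotspot_distance = 6,       # A, hotspot membership distance
    pH = 7,                     # surrogate charge term
    seed_threshold = -1,        # z-scale hotspot seed rule
    exposure_threshold = 0.25,  # relative SASA
    buried_weight = 0.2,        # patch weight of buried residues
    hotspot_score = "corrected",
    contact_cutoff = 4.5,       # A, heavy-atom contact rule
    contact_min_sep = 2,        # residues, near-diagonal exclusion
    projection_norm = "l1",
    mask_k = 1,                 # most-affected = mean + k*sd
    active_mode = "union",
    probe_radius = 1.4,         # A
    sasa_points = 960,
    sasa_reference = "isolated",
    cluster_atoms = "calpha",
    seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "vhh_config")
}

#' Write a resolved configuration as JSON
#'
#' @param cfg a `vhh_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
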