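#' Pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults, as one flat
#' list. Unknown keys are rejected so a typo never silently falls back to a
#' default. The resolved configuration is recorded in every run manifest.
#'
#' Key parameters (units in names where applicable):
#' * `min_contact_area_um2` — adjacency edges below this interface area are
#'   dropped (segmentation speckle), default 1 um^2.
#' * `continuity_threshold_deg` — junction wall angle at or above which a
#'   daughter pair counts as a recent division, default 160 degrees.
#' * `periclinal_max_deg`, `anticlinal_min_deg` — orientation bands: wall
#'   normal within 30 degrees of the local radial direction is periclinal,
#'   beyond 60 degrees anticlinal, oblique between.
#' * `min_side_area_um2` — minimum side-wall patch area for a junction angle
#'   measurement, default 4 um^2.
#' * `curvature_radius_um`, `curvature_radius_small_um`,
#'   `small_ovule_diameter_um` — curvature neighborhood of 40 um, reduced to
#'   30 um when the mesh bounding-sphere diameter is below 80 um.
#' * `n_plane_directions` — size of the half-sphere direction grid for
#'   shortest-wall plane search, default 500.
#' * `staging_k` — default number of developmental stages fitted, 4.
#' * `seed` — integer seed governing all stochastic steps.
#'
#' @param ... overrides of the defaults by name.
#' @return a named list of class `primordium_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    min_contact_area_um2 = 1.0,
    continuity_threshold_deg = 160,
    periclinal_max_deg = 30,
    anticlinal_min_deg = 60,
    min_side_area_um2 = 4.0,
    curvature_radius_um = 40,
    curvature_radius_small_um = 30,
    small_ovule_diameter_um = 80,
    n_plane_directions = 500L,
    plane_refine_iters = 2L,
    mesh_smoothing_iters = 10L,
    mask_smoothing_sigma_vox = 0.6,
    staging_k = 4L,
    staging_k_max = 8L,
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = c("primordium_config", "list"))
}

#' Read / write a pipeline configuration (YAML)
#' @param path YAML file path.
#' @param config a configuration from [default_config()].
#' @return `read_config()` returns the merged config (file values over
#'   defaults, unknown keys rejected); `write_config()` returns `path`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
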