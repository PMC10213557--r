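#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> annotate -> measure -> stage -> divisions ->
#' organ shape -> summary as one reproducible run. Inputs are either a
#' synthetic cohort (as from [generate_cohort()]) or a character vector of
#' labeled-volume file paths. Outputs are written as CSV tables plus a YAML
#' run manifest capturing the resolved configuration, input hashes, seed and
#' timestamps; re-running with the same manifest inputs reproduces all
#' outputs.
#'
#' @param inputs a cohort list (`list(volume, truth)` elements) or file
#'   paths.
#' @param out_dir output directory (created if needed).
#' @param config a [default_config()].
#' @param voxel_size voxel size override for file inputs lacking metadata.
#' @return a `run_manifest` list (invisibly writes `cells_measured.csv`,
#'   `stages.csv`, `divisions.csv`, `ovule_shape.csv`, `summary.csv`,
#'   `manifest.yaml` in `out_dir`).
#' @export
run_pipeline <- function(inputs, out_dir, config = default_config(),
                         voxel_size = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), seed = config$seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   version = as.character(utils::packageVersion(
                     "primordium3d")),
                   inputs = list(), outputs = list(), status = "running")
  load_ovule <- function(inp, id) {
    if (is.character(inp)) {
      manifest$inputs[[id]] <<- list(path = inp,
                                     md5 = unname(tools::md5sum(inp)))
      list(volume = read_labeled_volume(inp, voxel_size = voxel_size),
           truth = NULL)
    } else {
      manifest$inputs[[id]] <<- list(path = "<in-memory>", md5 = NA)
      inp
    }
  }
  ids <- if (!is.null(names(inputs)) && is.list(inputs)) names(inputs)
  else sprintf("ovule_%03d", seq_along(inputs))
  if (is.character(inputs)) inputs <- as.list(inputs)

  cells <- list(); div <- list(); shapes <- list()
  failed_at <- NULL
  for (q in seq_along(inputs)) {
    id <- ids[q]
    step <- "load"
    res <- tryCatch({
      ov <- load_ovule(inputs[[q]], id)
      step <- "annotate"
      ann <- annotate_ovule(ov$volume, config)
      step <- "measure"
      ct <- measure_cells(ov$volume, ann, ovule_id = id, config = config)
      step <- "divisions"
      dv <- detect_recent_divisions(ov$volume, ann, config)
      dv <- dplyr::mutate(dv, ovule_id = id, .before = 1)
      step <- "organ"
      obb <- oriented_bounding_box(ov$volume, ann$layers)
      sh <- tibble::tibble(
        ovule_id = id,
        box_a_um = obb$lengths[1], box_b_um = obb$lengths[2],
        box_c_um = obb$lengths[3], aspect_ratio = obb$aspect_ratio,
        central_l2 = ann$central_l2,
        central_l3 = ifelse(is.na(ann$central_l3), NA_integer_,
                            ann$central_l3))
      list(cells = ct, div = dv, sh = sh)
    }, error = function(e) {
      message("pipeline failed for ", id, " at stage '", step, "': ",
              conditionMessage(e))
      failed_at <<- c(failed_at, paste0(id, ":", step))
      NULL
    })
    if (!is.null(res)) {
      cells[[id]] <- res$cells; div[[id]] <- res$div; shapes[[id]] <- res$sh
    }
  }
  if (length(cells) == 0L) stop("no ovule processed successfully")
  cell_tab <- dplyr::bind_rows(cells)
  div_tab <- dplyr::bind_rows(div)
  shape_tab <- dplyr::bind_rows(shapes)

  # staging on central L2 cell volumes
  central <- cell_tab |>
    dplyr::filter(.data$contact_class == "central_L2") |>
    dplyr::group_by(.data$ovule_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  stage_tab <- tibble::tibble(ovule_id = central$ovule_id,
                              central_l2_volume_um3 = central$volume_um3,
                              stage = NA_integer_)
  if (nrow(central) >= config$staging_k) {
    sm <- assign_stages(central$volume_um3, k = config$staging_k)
    stage_tab$stage <- sm$assignments
  }
  cell_tab$stage <- stage_tab$stage[match(cell_tab$ovule_id,
                                          stage_tab$ovule_id)]
  summary_tab <- group_summary(cell_tab)

  paths <- list(cells = file.path(out_dir, "cells_measured.csv"),
                stages = file.path(out_dir, "stages.csv"),
                divisions = file.path(out_dir, "divisions.csv"),
                shape = file.path(out_dir, "ovule_shape.csv"),
                summary = file.path(out_dir, "summary.csv"))
  write_cell_table(cell_tab, paths$cells)
  readr::write_csv(stage_tab, paths$stages, progress = FALSE)
  readr::write_csv(div_tab, paths$divisions, progress = FALSE)
  readr::write_csv(shape_tab, paths$shape, progress = FALSE)
  readr::write_csv(dplyr::select(summary_tab, -dplyr::any_of("n_list")),
                   paths$summary, progress = FALSE)
  manifest$outputs <- lapply(paths, normalizePath)
  manifest$status <- if (is.null(failed_at)) "complete" else
    paste("failed at:", paste(failed_at, collapse = ", "))
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  structure(manifest, class = "run_manifest")
}

#' Report tables and colored meshes from pipeline outputs
#'
#' Builds figure-style pivot tables (cell class x stage mean descriptor
#' grids) from a pipeline output directory, and optionally exports
#' heat-map-colored ovule meshes (per-cell descriptor painted on each cell's
#' surface) when the volumes are provided.
#'
#' @param out_dir directory holding `cells_measured.csv`.
#' @param descriptors descriptor columns to pivot.
#' @param cohort optional cohort list to render colored meshes from.
#' @param descriptor_mesh descriptor painted on meshes.
#' @return list of pivot tibbles (one per descriptor), written as
#'   `report_<descriptor>.csv`; colored meshes as `<ovule>_colored.ply`.
#' @export
make_report <- function(out_dir,
                        descriptors = c("volume_um3", "norm_axis_c",
                                        "sphericity"),
                        cohort = NULL, descriptor_mesh = "volume_um3") {
  cells <- read_cell_table(file.path(out_dir, "cells_measured.csv"))
  out <- list()
  for (d in descriptors) {
    pv <- cells |>
      dplyr::filter(!is.na(.data$stage), !is.na(.data[[d]])) |>
      dplyr::group_by(.data$contact_class, .data$stage) |>
      dplyr::summarise(mean = mean(.data[[d]]), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "stage", values_from = "mean",
                         names_prefix = "stage_")
    if (nrow(pv) == 0L)
      message("report: no staged cells for descriptor ", d)
    readr::write_csv(pv, file.path(out_dir, paste0("report_", d, ".csv")),
                     progress = FALSE)
    out[[d]] <- pv
  }
  if (!is.null(cohort)) {
    for (id in names(cohort)) {
      vol <- cohort[[id]]$volume
      sub <- cells[cells$ovule_id == id, ]
      if (nrow(sub) == 0L) next
      mesh <- export_colored_mesh(
        vol, sub, descriptor_mesh,
        file.path(out_dir, paste0(id, "_colored.ply")))
    }
  }
  invisible(out)
}

#' Export an ovule mesh colored by a per-cell descriptor
#'
#' Concatenates the surface meshes of all cells, painting each cell's
#' vertices with its descriptor value as the PLY scalar channel (the
#' heat-map rendering of relative cell volume or anisotropy).
#'
#' @param volume a [labeled_volume()].
#' @param cell_table measured cells of this ovule.
#' @param descriptor column to paint.
#' @param path output `.ply` path.
#' @return the combined [surface_mesh()], invisibly.
#' @export
export_colored_mesh <- function(volume, cell_table, descriptor, path) {
  labs <- intersect(cell_labels(volume), cell_table$cell_label)
  verts <- list(); tris <- list(); scal <- list()
  off <- 0L
  for (l in labs) {
    val <- cell_table[[descriptor]][cell_table$cell_label == l][1]
    if (is.na(val)) next
    m <- tryCatch(extract_cell_mesh(volume, l, smoothing_iters = 3L)$mesh,
                  error = function(e) NULL)
    if (is.null(m)) next
    verts[[length(verts) + 1L]] <- m$vertices
    tris[[length(tris) + 1L]] <- m$triangles + off
    scal[[length(scal) + 1L]] <- rep(val, nrow(m$vertices))
    off <- off + nrow(m$vertices)
  }
  mesh <- surface_mesh(do.call(rbind, verts), do.call(rbind, tris),
                       scalar = unlist(scal))
  export_mesh(mesh, path)
  invisible(mesh)
}
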