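# Schema of the per-cell descriptor table, the tabular backbone of the
# pipeline. One row per (ovule_id, cell_label).
cell_table_columns <- function() {
  c(ovule_id = "character", cell_label = "integer", layer = "character",
    contact_class = "character", volume_um3 = "double",
    semi_axis_a = "double", semi_axis_b = "double", semi_axis_c = "double",
    norm_axis_a = "double", norm_axis_b = "double", norm_axis_c = "double",
    two_axis_anisotropy = "double", sphericity = "double",
    prolate_ellipticity = "double", oblate_ellipticity = "double",
    surface_area_um2 = "double", apical_wall_area_um2 = "double",
    basal_wall_area_um2 = "double", stage = "integer")
}

valid_layers <- c("L1", "L2", "L3", "L4")
valid_contact_classes <- c("central_L2", "central_L3", "contact1", "contact2",
                           "contact_gt2", "other")

#' Validate a cell descriptor table
#'
#' Checks column presence and types, the semi-axis ordering `a <= b <= c`,
#' that the normalized ellipsoid axes sum to 1, and the layer / contact-class
#' vocabularies. Missing values are allowed in descriptor columns (a flagged
#' per-cell failure leaves NAs) but not in the key columns.
#'
#' @param table a data frame following the cell-table schema.
#' @return the table as a tibble, invisibly usable; errors list every
#'   offending column.
#' @export
validate_cell_table <- function(table) {
  table <- tibble::as_tibble(table)
  cols <- cell_table_columns()
  bad <- character()
  missing <- setdiff(names(cols), names(table))
  if (length(missing))
    stop("cell table missing columns: ", paste(missing, collapse = ", "))
  if (any(is.na(table$ovule_id)) || any(is.na(table$cell_label)))
    bad <- c(bad, "ovule_id/cell_label (missing keys)")
  if (!all(is.na(table$layer) | table$layer %in% valid_layers))
    bad <- c(bad, "layer")
  if (!all(is.na(table$contact_class) |
           table$contact_class %in% valid_contact_classes))
    bad <- c(bad, "contact_class")
  ok_axes <- is.na(table$semi_axis_a) | is.na(table$semi_axis_b) |
    is.na(table$semi_axis_c) |
    (table$semi_axis_a <= table$semi_axis_b + 1e-9 &
     table$semi_axis_b <= table$semi_axis_c + 1e-9)
  if (!all(ok_axes)) bad <- c(bad, "semi_axis_a/b/c (ordering a <= b <= c)")
  ssum <- table$norm_axis_a + table$norm_axis_b + table$norm_axis_c
  if (!all(is.na(ssum) | abs(ssum - 1) < 1e-9))
    bad <- c(bad, "norm_axis_a/b/c (must sum to 1)")
  if (!all(is.na(table$stage) | table$stage %in% 0:4))
    bad <- c(bad, "stage")
  if (length(bad))
    stop("cell table schema violation in: ", paste(bad, collapse = "; "))
  table
}

#' Read / write a cell descriptor table (CSV)
#'
#' CSV with header, UTF-8, "." decimal; numeric columns round-trip at full
#' double precision. The schema is validated on both paths.
#'
#' @param table a validated cell table.
#' @param path CSV file path.
#' @return `write_cell_table()` returns `path` invisibly;
#'   `read_cell_table()` returns the tibble.
#' @export
write_cell_table <- function(table, path) {
  table <- validate_cell_table(table)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  cols <- cell_table_columns()
  spec <- do.call(readr::cols, lapply(cols, function(tp)
    switch(tp, character = readr::col_character(),
           integer = readr::col_integer(), readr::col_double())))
  tab <- readr::read_csv(path, col_types = spec, progress = FALSE)
  validate_cell_table(tab)
}

# empty prototype row set
empty_cell_table <- function() {
  cols <- cell_table_columns()
  tibble::as_tibble(lapply(cols, function(tp) vector(tp, 0L)))
}
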