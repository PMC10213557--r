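#' Assign cell layers L1-L4 from the adjacency graph
#'
#' L1 are cells in contact with the exterior surface (the `base_plane` face
#' does not count as exterior); each following layer is the set of
#' still-unassigned cells adjacent to the previous one; every cell at graph
#' distance greater than 3 from the exterior is labeled L4. Cells unreachable
#' from the exterior raise a warning and are labeled L4.
#'
#' @param graph an [build_adjacency()] result.
#' @return named character vector, `names` = cell labels, values L1-L4.
#' @export
assign_layers <- function(graph) {
  g <- graph$graph
  labs <- setdiff(igraph::V(g)$name, "EXTERIOR")
  d <- igraph::distances(g, v = "EXTERIOR", to = labs)[1, ]
  if (any(!is.finite(d))) {
    warning(sum(!is.finite(d)), " cell(s) unreachable from EXTERIOR; ",
            "labeled L4")
    d[!is.finite(d)] <- 4
  }
  layer <- paste0("L", pmin(pmax(as.integer(d), 1L), 4L))
  stats::setNames(layer, labs)
}

# Apical axis of the ovule: principal axis of the L1 exterior-contact face
# cloud that is best aligned with the grid z axis, oriented away from the
# base plane. Falls back to the grid z axis for near-isotropic clouds.
apical_axis_from_cloud <- function(graph, layers) {
  l1 <- as.integer(names(layers)[layers == "L1"])
  f <- graph$faces
  if (is.null(f)) stop("adjacency graph built with keep_faces = FALSE")
  ext <- f[f$a == 0L & f$b %in% l1, c("x", "y", "z"), drop = FALSE]
  if (nrow(ext) < 10L) return(list(axis = c(0, 0, 1),
                                   origin = c(0, 0, 0)))
  m <- as.matrix(ext)
  ctr <- colMeans(m)
  ev <- eigen(stats::cov(m), symmetric = TRUE)
  if (max(ev$values) / max(min(ev$values), 1e-12) < 1.2) {
    ax <- c(0, 0, 1)
  } else {
    ali <- abs(ev$vectors[3, ])
    ax <- ev$vectors[, which.max(ali)]
    if (ax[3] < 0) ax <- -ax   # away from the z-min base plane
  }
  list(axis = ax, origin = ctr)
}

#' Identify the most apical central L2 cell
#'
#' Returns the L2 cell reaching highest along the apical (dome) axis,
#' measured by the 95th percentile of its voxel projections (its apical
#' reach). The reach, unlike the centroid, does not penalize an elongated
#' cell whose mass extends basally — the megaspore mother cell's apex
#' touches the dome apex even when its centroid lies deep. Near ties
#' (reaches within 0.5 um) are broken by the smaller perpendicular centroid
#' distance to the axis line, preferring the on-axis (central) candidate.
#'
#' @param volume a [labeled_volume()].
#' @param layers layer assignment from [assign_layers()].
#' @param graph the adjacency graph (for the default apical axis).
#' @param apical_axis optional unit 3-vector `(x, y, z)` override.
#' @return the selected cell label (integer).
#' @export
identify_central_l2 <- function(volume, layers, graph = NULL,
                                apical_axis = NULL) {
  l2 <- as.integer(names(layers)[layers == "L2"])
  if (length(l2) == 0L) stop("no L2 cell in volume")
  if (is.null(apical_axis)) {
    if (is.null(graph)) stop("need `graph` or an explicit `apical_axis`")
    aa <- apical_axis_from_cloud(graph, layers)
  } else {
    aa <- list(axis = apical_axis / sqrt(sum(apical_axis^2)),
               origin = colMeans(do.call(rbind,
                 lapply(l2, function(l) colMeans(cell_coords(volume, l))))))
  }
  coords_by_cell <- lapply(l2, function(l) cell_coords(volume, l))
  cent <- t(vapply(coords_by_cell, colMeans, numeric(3)))
  proj <- vapply(coords_by_cell, function(cc)
    quantile(as.vector(cc %*% aa$axis), 0.95, names = FALSE), numeric(1))
  top <- max(proj)
  cand <- which(proj >= top - 0.5)
  if (length(cand) > 1L) {
    rel <- sweep(cent[cand, , drop = FALSE], 2, aa$origin)
    par <- as.vector(rel %*% aa$axis)
    perp2 <- rowSums(rel^2) - par^2
    cand <- cand[which.min(perp2)]
  }
  l2[cand[1]]
}

#' Contact-degree classes around the central L2 cell
#'
#' Breadth-first classes in the cell adjacency graph truncated at distance 2:
#' neighbors of the central cell are `contact1`, their unclassified neighbors
#' `contact2`, everything further `contact_gt2`. Classes cross-cut layers.
#'
#' @param graph an [build_adjacency()] result.
#' @param central_label the central L2 cell.
#' @return named character vector over all cells: `central_L2`, `contact1`,
#'   `contact2`, or `contact_gt2`.
#' @export
assign_contact_degrees <- function(graph, central_label) {
  g <- igraph::delete_vertices(graph$graph, "EXTERIOR")
  labs <- igraph::V(g)$name
  if (!as.character(central_label) %in% labs)
    stop("central label ", central_label, " not in graph")
  d <- igraph::distances(g, v = as.character(central_label), to = labs)[1, ]
  cls <- dplyr::case_when(d == 0 ~ "central_L2",
                          d == 1 ~ "contact1",
                          d == 2 ~ "contact2",
                          TRUE ~ "contact_gt2")
  stats::setNames(cls, labs)
}

#' Select the central L3 (stack) cell
#'
#' Among L3 cells adjacent to the central L2 cell, selects the one best
#' aligned with the central L2 cell's major ellipsoid axis on its basal side:
#' the candidate minimizing the angle between its centroid displacement from
#' the central L2 centroid and the basal-ward major axis.
#'
#' @param graph an [build_adjacency()] result.
#' @param volume a [labeled_volume()].
#' @param central_l2 the central L2 label.
#' @param layers layer assignment.
#' @param major_axis unit major axis of the central L2 ellipsoid fit; when
#'   `NULL` it is fitted here.
#' @param apical_axis unit apical axis used to orient the major axis
#'   basal-ward (defaults to +z).
#' @return the selected L3 label, or `NA_integer_` if no L3 neighbor exists.
#' @export
select_central_l3 <- function(graph, volume, central_l2, layers,
                              major_axis = NULL, apical_axis = c(0, 0, 1)) {
  nb <- cell_neighbors(graph, central_l2)
  l3 <- nb[layers[as.character(nb)] == "L3"]
  l3 <- l3[!is.na(l3)]
  if (length(l3) == 0L) return(NA_integer_)
  if (is.null(major_axis)) {
    fit <- fit_ellipsoid(volume, central_l2)
    major_axis <- fit$axes[, 3]
  }
  # the cell axis is meaningful only when it runs apical-basal; a freshly
  # divided (oblate) central cell has an equatorial major axis, in which
  # case the dome axis is the reference instead
  if (op_angle(major_axis, apical_axis) > 45) major_axis <- apical_axis
  basal <- if (sum(major_axis * apical_axis) > 0) -major_axis else major_axis
  c0 <- colMeans(cell_coords(volume, central_l2))
  ang <- vapply(l3, function(l) {
    v <- colMeans(cell_coords(volume, l)) - c0
    v <- v / sqrt(sum(v^2))
    acos(pmin(pmax(sum(v * basal), -1), 1))
  }, numeric(1))
  l3[which.min(ang)]
}

#' Full two-level annotation of one ovule
#'
#' Runs layer assignment, central L2 identification, contact-degree classes
#' and central L3 selection, reproducing the two-level cell-type annotation
#' (layers plus radial position) used for the 11-cell-type atlas.
#'
#' @param volume a [labeled_volume()].
#' @param config a [default_config()].
#' @param graph optional precomputed adjacency graph.
#' @return an `ovule_annotation` list: `layers`, `contact_class` (with the
#'   central L3 recoded `central_L3`), `central_l2`, `central_l3`,
#'   `apical_axis`, `graph`.
#' @export
annotate_ovule <- function(volume, config = default_config(), graph = NULL) {
  if (is.null(graph))
    graph <- build_adjacency(volume, config$min_contact_area_um2)
  layers <- assign_layers(graph)
  aa <- apical_axis_from_cloud(graph, layers)
  central <- identify_central_l2(volume, layers, graph)
  classes <- assign_contact_degrees(graph, central)
  fit <- tryCatch(fit_ellipsoid(volume, central), error = function(e) NULL)
  l3 <- select_central_l3(graph, volume, central, layers,
                          major_axis = if (is.null(fit)) NULL else
                            fit$axes[, 3],
                          apical_axis = aa$axis)
  if (!is.na(l3)) classes[as.character(l3)] <- "central_L3"
  structure(list(layers = layers, contact_class = classes,
                 central_l2 = central, central_l3 = l3,
                 apical_axis = aa$axis, apical_origin = aa$origin,
                 graph = graph),
            class = "ovule_annotation")
}

#' @exportS3Method base::print
print.ovule_annotation <- function(x, ...) {
  cat(sprintf(
    "<ovule_annotation> %d cells; central L2 = %d, central L3 = %s\n",
    length(x$layers), x$central_l2,
    ifelse(is.na(x$central_l3), "absent", x$central_l3)))
  cat("  layers:", paste(names(table(x$layers)), table(x$layers),
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}
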