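#' Cell-contact adjacency graph
#'
#' Builds the cell adjacency network of a labeled volume: nodes are cell
#' labels plus a virtual `EXTERIOR` node, edges connect labels sharing at
#' least one voxel face (6-connectivity) and carry the shared interface area
#' in um^2 (voxel-face count times face area). Contacts with the background
#' count as `EXTERIOR` except on the `base_plane` face, where the crop
#' continues into tissue.
#'
#' @param volume a [labeled_volume()].
#' @param min_contact_area edges with interface area below this (um^2) are
#'   dropped as segmentation speckle.
#' @param keep_faces keep the per-face table (needed downstream by wall
#'   geometry and junction angles; costs memory on large volumes).
#' @return an object of class `adjacency_graph`: a list with `edges`
#'   (tibble: a, b, area_um2, n_faces; `b = 0` encodes EXTERIOR), `graph`
#'   (igraph, with an `EXTERIOR` vertex), and optionally `faces`.
#' @export
build_adjacency <- function(volume, min_contact_area = 1.0,
                            keep_faces = TRUE) {
  vs <- volume$voxel_size
  f <- .label_faces_cpp(as.vector(volume$labels), dim(volume$labels), vs)
  faces <- tibble::tibble(a = f$a, b = f$b, axis = f$axis,
                          x = f$x, y = f$y, z = f$z)
  # canonical order, drop base-plane exterior faces from the EXTERIOR contact
  swap <- faces$a > faces$b
  tmp <- faces$a[swap]; faces$a[swap] <- faces$b[swap]; faces$b[swap] <- tmp
  if (volume$base_plane == "zmin") {
    base <- faces$a == 0L & faces$axis == 1L & faces$z < vs[1] * 0.5
    faces <- faces[!base, , drop = FALSE]
  }
  face_area <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2]) # z-, y-, x-normal
  faces$area <- face_area[faces$axis]
  edges <- faces |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(area_um2 = sum(.data$area), n_faces = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$area_um2 >= min_contact_area)
  labs <- cell_labels(volume)
  vnames <- c("EXTERIOR", as.character(labs))
  enames <- cbind(ifelse(edges$a == 0L, "EXTERIOR", as.character(edges$a)),
                  as.character(edges$b))
  g <- igraph::graph_from_edgelist(enames, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(vnames, igraph::V(g)$name)),
                            name = setdiff(vnames, igraph::V(g)$name))
  igraph::E(g)$area_um2 <- edges$area_um2
  structure(list(edges = edges, graph = g,
                 faces = if (keep_faces) faces else NULL,
                 voxel_size = vs),
            class = "adjacency_graph")
}

#' @exportS3Method base::print
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> %d cells, %d contacts (%d with EXTERIOR)\n",
              igraph::vcount(x$graph) - 1L, nrow(x$edges),
              sum(x$edges$a == 0L)))
  invisible(x)
}

#' Interface area between two cells (or a cell and EXTERIOR)
#' @param graph an [build_adjacency()] result.
#' @param a,b cell labels; use 0 or `"EXTERIOR"` for the outside.
#' @return area in um^2 (0 when not adjacent).
#' @export
contact_area <- function(graph, a, b) {
  a <- if (identical(a, "EXTERIOR")) 0L else as.integer(a)
  b <- if (identical(b, "EXTERIOR")) 0L else as.integer(b)
  lo <- min(a, b); hi <- max(a, b)
  hit <- graph$edges$a == lo & graph$edges$b == hi
  if (!any(hit)) 0 else sum(graph$edges$area_um2[hit])
}

# neighbors of a cell label (excluding EXTERIOR unless include_exterior)
cell_neighbors <- function(graph, label, include_exterior = FALSE) {
  e <- graph$edges
  nb <- c(e$b[e$a == label], e$a[e$b == label])
  if (!include_exterior) nb <- nb[nb != 0L]
  sort(unique(nb))
}
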