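#' Triangulated surface mesh
#'
#' Vertices in physical um coordinates plus a triangle index matrix, with an
#' optional per-vertex scalar channel (e.g. curvature) carried alongside.
#'
#' @param vertices numeric matrix, columns x, y, z (um).
#' @param triangles integer matrix, 3 columns of 1-based vertex indices.
#' @param scalar optional numeric per-vertex channel.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, scalar = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle index out of range")
  if (!is.null(scalar) && length(scalar) != nrow(vertices))
    stop("scalar channel length must match vertex count")
  colnames(vertices) <- c("x", "y", "z")
  structure(list(vertices = vertices, triangles = triangles, scalar = scalar),
            class = "surface_mesh")
}

#' @exportS3Method base::print
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, area %.4g um^2%s\n",
              nrow(x$vertices), nrow(x$triangles), mesh_area(x),
              if (is.null(x$scalar)) "" else ", scalar channel"))
  invisible(x)
}

#' Total surface area of a mesh
#' @param mesh a [surface_mesh()].
#' @return area in um^2.
#' @export
mesh_area <- function(mesh) {
  tri <- mesh$triangles
  if (nrow(tri) == 0L) return(0)
  v <- mesh$vertices
  e1 <- v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  e2 <- v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# Deduplicate a triangle soup (vertices repeated per triangle) into an
# indexed mesh; coordinates are matched after rounding to `digits`.
dedupe_soup <- function(vertices, triangles, digits = 6L) {
  key <- paste(round(vertices[, 1], digits), round(vertices[, 2], digits),
               round(vertices[, 3], digits))
  uid <- match(key, unique(key))
  first <- !duplicated(key)
  verts <- vertices[first, , drop = FALSE]
  tris <- matrix(uid[as.vector(t(triangles))], ncol = 3, byrow = TRUE)
  # drop degenerate triangles (two identical corners after rounding)
  ok <- tris[, 1] != tris[, 2] & tris[, 2] != tris[, 3] & tris[, 1] != tris[, 3]
  surface_mesh(verts, tris[ok, , drop = FALSE])
}

#' Isosurface of a binary mask
#'
#' Extracts a triangulated surface of a 3D logical mask: the mask is Gaussian
#' smoothed (to suppress voxel staircase artifacts that would bias areas) and
#' contoured at level 0.5 by marching tetrahedra with linear interpolation,
#' then optionally Taubin smoothed. Coordinates are physical um.
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @param voxel_size `(dz, dy, dx)` um.
#' @param sigma_vox Gaussian pre-smoothing sigma in voxels (0 disables).
#' @param smoothing_iters Taubin smoothing iterations on the mesh.
#' @return a [surface_mesh()].
#' @export
mask_isosurface <- function(mask, voxel_size, sigma_vox = 0.6,
                            smoothing_iters = 10L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  # pad with background so surfaces at the grid boundary are closed
  d <- dim(mask)
  pad <- array(FALSE, d + 4L)
  pad[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- mask
  field <- if (sigma_vox > 0) smooth_field(pad * 1, sigma_vox) else pad * 1
  res <- .march_tetra_cpp(as.vector(field), dim(field),
                          as.numeric(voxel_size), 0.5)
  if (nrow(res$vertices) == 0L)
    stop("empty isosurface: mask has no interior at the 0.5 level")
  mesh <- dedupe_soup(res$vertices, res$triangles)
  # undo the 2-voxel pad offset
  off <- 2 * voxel_size[c(3, 2, 1)]
  mesh$vertices <- sweep(mesh$vertices, 2, off)
  if (smoothing_iters > 0L) mesh <- taubin_smooth(mesh, smoothing_iters)
  mesh
}

#' Taubin lambda/mu mesh smoothing
#'
#' Two-step Laplacian smoothing with a positive (`lambda`) then negative
#' (`mu`) factor, which smooths without the volume shrinkage of plain
#' Laplacian iteration.
#'
#' @param mesh a [surface_mesh()].
#' @param iterations number of lambda/mu passes.
#' @param lambda,mu Taubin factors (`0 < lambda < -mu`).
#' @return the smoothed mesh.
#' @export
taubin_smooth <- function(mesh, iterations = 5L, lambda = 0.5, mu = -0.53) {
  nv <- nrow(mesh$vertices)
  tri <- mesh$triangles
  if (nv < 4L || nrow(tri) == 0L) return(mesh)
  ii <- c(tri[, 1], tri[, 2], tri[, 2], tri[, 3], tri[, 3], tri[, 1])
  jj <- c(tri[, 2], tri[, 1], tri[, 3], tri[, 2], tri[, 1], tri[, 3])
  adj <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nv, nv))
  adj@x[] <- 1  # collapse duplicate edges
  deg <- Matrix::rowSums(adj)
  deg[deg == 0] <- 1
  w <- adj / deg
  v <- mesh$vertices
  for (it in seq_len(iterations)) {
    v <- v + lambda * (as.matrix(w %*% v) - v)
    v <- v + mu * (as.matrix(w %*% v) - v)
  }
  mesh$vertices <- v
  mesh
}

#' Export a mesh to OBJ or PLY
#'
#' OBJ stores geometry only; ASCII PLY additionally stores the per-vertex
#' scalar channel (as property `quality`) when present.
#'
#' @param mesh a [surface_mesh()].
#' @param path destination ending in `.obj` or `.ply`.
#' @param scalar optional per-vertex channel overriding `mesh$scalar`.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path, scalar = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(scalar)) scalar <- mesh$scalar
  if (!is.null(scalar) && length(scalar) != nrow(mesh$vertices))
    stop("scalar channel length must match vertex count")
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  tri <- mesh$triangles
  if (ext == "obj") {
    lines <- c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", tri[, 1], tri[, 2], tri[, 3]))
    writeLines(lines, path)
  } else if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property float x", "property float y", "property float z",
             if (!is.null(scalar)) "property float quality",
             sprintf("element face %d", nrow(tri)),
             "property list uchar int vertex_indices",
             "end_header")
    vl <- if (is.null(scalar))
      sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
    else
      sprintf("%.9g %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3], scalar)
    fl <- sprintf("3 %d %d %d", tri[, 1] - 1L, tri[, 2] - 1L, tri[, 3] - 1L)
    writeLines(c(hdr, vl, fl), path)
  } else {
    stop("unsupported mesh format: .", ext)
  }
  invisible(path)
}

#' Import a mesh from OBJ or PLY
#' @param path source path ending in `.obj` or `.ply`.
#' @return a [surface_mesh()]; PLY `quality` becomes the scalar channel.
#' @export
import_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "obj") {
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
      as.numeric(x[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
    surface_mesh(v, f)
  } else if (ext == "ply") {
    end <- which(lines == "end_header")[1]
    nvert <- as.integer(sub("element vertex ", "",
                            grep("^element vertex", lines, value = TRUE)[1]))
    nface <- as.integer(sub("element face ", "",
                            grep("^element face", lines, value = TRUE)[1]))
    props <- grep("^property float", lines[seq_len(end)], value = TRUE)
    has_q <- any(grepl("quality", props))
    vlines <- lines[(end + 1):(end + nvert)]
    vm <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), as.numeric))
    flines <- lines[(end + nvert + 1):(end + nvert + nface)]
    fm <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(x)
      as.integer(x[2:4]) + 1L))
    surface_mesh(vm[, 1:3, drop = FALSE], fm,
                 scalar = if (has_q) vm[, 4] else NULL)
  } else {
    stop("unsupported mesh format: .", ext)
  }
}
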