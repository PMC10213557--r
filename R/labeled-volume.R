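#' Labeled 3D volume
#'
#' Container for a segmented, labeled 3D image: an integer label grid
#' (0 = background, one positive label per cell) together with the physical
#' voxel size. The array is indexed `(z, y, x)` with the first index fastest;
#' the physical center of 1-based voxel `(k, j, i)` is
#' `((i - 0.5) dx, (j - 0.5) dy, (k - 0.5) dz)` in micrometres.
#'
#' The `base_plane` is the grid face where the crop terminates in tissue
#' rather than free surface (ovule crops are cut from ear sections at their
#' base); that face is excluded when deciding which cells touch the exterior.
#'
#' @param labels integer 3D array, `dim = c(nz, ny, nx)`; 0 is background.
#' @param voxel_size numeric length-3, `(dz, dy, dx)` in um, all positive.
#' @param base_plane which grid face continues into tissue; currently only
#'   `"zmin"` (the default) is meaningful for dome-shaped crops.
#' @return an object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, voxel_size, base_plane = "zmin") {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (!is.integer(labels)) {
    if (any(labels != round(labels)))
      stop("`labels` must be integer-valued")
    storage.mode(labels) <- "integer"
  }
  if (any(labels < 0L)) stop("labels must be >= 0")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers (dz, dy, dx) in um")
  base_plane <- match.arg(base_plane, "zmin")
  structure(
    list(labels = labels, voxel_size = voxel_size, base_plane = base_plane),
    class = "labeled_volume"
  )
}

#' @exportS3Method base::print
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "<labeled_volume> %d x %d x %d voxels (z,y,x), voxel %.3g x %.3g x %.3g um\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  labs <- cell_labels(x)
  cat(sprintf("  %d cells, foreground %.4g um^3, base plane %s\n",
              length(labs), foreground_volume(x), x$base_plane))
  invisible(x)
}

#' Cell labels present in a volume
#' @param volume a [labeled_volume()].
#' @return sorted integer vector of the nonzero labels present.
#' @export
cell_labels <- function(volume) {
  u <- sort(unique(as.vector(volume$labels)))
  u[u > 0L]
}

#' @rdname cell_labels
#' @return `voxel_volume()`: the volume of one voxel in um^3.
#' @export
voxel_volume <- function(volume) prod(volume$voxel_size)

#' @rdname cell_labels
#' @return `foreground_volume()`: total labeled volume in um^3.
#' @export
foreground_volume <- function(volume) {
  sum(volume$labels > 0L) * voxel_volume(volume)
}

# physical (x, y, z) centers of the voxels at 1-based array indices
# idx: integer matrix with columns (k, j, i)
voxel_centers <- function(idx, voxel_size) {
  cbind(x = (idx[, 3] - 0.5) * voxel_size[3],
        y = (idx[, 2] - 0.5) * voxel_size[2],
        z = (idx[, 1] - 0.5) * voxel_size[1])
}

# indices (k, j, i) of all voxels of one label
label_indices <- function(volume, label) {
  which(volume$labels == label, arr.ind = TRUE)
}

#' Physical voxel-center coordinates of one cell
#' @param volume a [labeled_volume()].
#' @param label cell label.
#' @return matrix with columns x, y, z (um), one row per voxel.
#' @export
cell_coords <- function(volume, label) {
  idx <- label_indices(volume, label)
  if (nrow(idx) == 0L) stop("label ", label, " not present in volume")
  voxel_centers(idx, volume$voxel_size)
}

# Squared Euclidean distance (um^2) to the nearest TRUE voxel of `feature`.
edt3d <- function(feature, voxel_size) {
  stopifnot(is.logical(feature), length(dim(feature)) == 3L)
  if (!any(feature)) stop("distance transform needs at least one feature voxel")
  d <- .edt3d_cpp(as.vector(feature), dim(feature), as.numeric(voxel_size))
  array(d, dim(feature))
}

# Exterior mask: background voxels 6-adjacent to foreground, plus the virtual
# exterior beyond the grid boundary. Returned as the mask of *background or
# out-of-grid adjacent* positions encoded on the grid: TRUE where a voxel is
# background, or a 1-voxel pad would be. For distance-to-exterior purposes we
# take the background voxels themselves plus grid-boundary foreground handled
# via padding.
exterior_distance <- function(volume, exclude_base = TRUE) {
  lab <- volume$labels
  d <- dim(lab)
  # pad the grid by one background voxel on each face; the base (z = min)
  # face is padded with foreground sentinel when excluded, so that tissue
  # continuing through the base is not counted as surface.
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- lab
  if (exclude_base && volume$base_plane == "zmin") {
    pad[1, 2:(d[2] + 1), 2:(d[3] + 1)] <- lab[1, , ]
  }
  feat <- pad == 0L
  dd <- edt3d(feat, volume$voxel_size)
  dd[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

# Local radial (outward) direction at physical point p = c(x, y, z):
# negative normalized gradient of the distance-to-exterior field.
# dist2 is the squared distance field on the full grid.
radial_direction <- function(dist2, voxel_size, p) {
  d <- dim(dist2)
  # 1-based voxel index containing p
  i <- min(max(ceiling(p[1] / voxel_size[3]), 2L), d[3] - 1L)
  j <- min(max(ceiling(p[2] / voxel_size[2]), 2L), d[2] - 1L)
  k <- min(max(ceiling(p[3] / voxel_size[1]), 2L), d[1] - 1L)
  dist <- sqrt(dist2)
  gx <- (dist[k, j, i + 1] - dist[k, j, i - 1]) / (2 * voxel_size[3])
  gy <- (dist[k, j + 1, i] - dist[k, j - 1, i]) / (2 * voxel_size[2])
  gz <- (dist[k + 1, j, i] - dist[k - 1, j, i]) / (2 * voxel_size[1])
  g <- c(gx, gy, gz)
  n <- sqrt(sum(g^2))
  if (n < 1e-12) return(c(0, 0, 1))
  -g / n
}

# Separable Gaussian smoothing of a 3D numeric array; sigma in voxels
# (scalar or per-axis (z, y, x)). Replicate-padding at the borders.
smooth_field <- function(arr, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  out <- arr
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    out <- convolve_axis(out, k, axis)
  }
  out
}

convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) / 2L
  acc <- array(0, d)
  n <- d[axis]
  for (o in -r:r) {
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)  # replicate padding
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    acc <- acc + kernel[o + r + 1L] * shifted
  }
  acc
}
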