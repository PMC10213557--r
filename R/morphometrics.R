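#' Cell volume
#' @param volume a [labeled_volume()].
#' @param label cell label.
#' @return voxel count times voxel volume, um^3.
#' @export
measure_volume <- function(volume, label) {
  n <- sum(volume$labels == label)
  if (n == 0L) stop("label ", label, " not present in volume")
  n * voxel_volume(volume)
}

#' Surface mesh and area of one cell
#'
#' Iso-surface of the binary cell mask (cropped to its bounding box with
#' padding), Gaussian pre-smoothed and Taubin smoothed; the surface area is
#' the triangle-area sum. Raw voxel-face counting is deliberately not used:
#' it overestimates oblique surfaces by up to ~50% and would corrupt
#' sphericity.
#'
#' @param volume a [labeled_volume()].
#' @param label cell label.
#' @param smoothing_iters Taubin iterations (default 5).
#' @param sigma_vox Gaussian pre-smoothing in voxels.
#' @return list with `mesh` (a [surface_mesh()]) and `area_um2`.
#' @export
extract_cell_mesh <- function(volume, label, smoothing_iters = 10L,
                              sigma_vox = 0.6) {
  idx <- label_indices(volume, label)
  if (nrow(idx) == 0L) stop("label ", label, " not present in volume")
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  thin <- (hi - lo + 1L) < 2L
  if (any(thin)) {
    warning("cell ", label, " thinner than 2 voxels; mesh not smoothed")
    smoothing_iters <- 0L
    sigma_vox <- 0.5
  }
  sub <- volume$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mask <- array(sub == label, dim = hi - lo + 1L)
  mesh <- mask_isosurface(mask, volume$voxel_size, sigma_vox = sigma_vox,
                          smoothing_iters = smoothing_iters)
  off <- (lo[c(3, 2, 1)] - 1L) * volume$voxel_size[c(3, 2, 1)]
  mesh$vertices <- sweep(mesh$vertices, 2, -off)
  list(mesh = mesh, area_um2 = mesh_area(mesh))
}

#' Fitting ellipsoid of a cell
#'
#' Second central moments of the voxel-center coordinates are
#' eigendecomposed; semi-axes are `sqrt(5 * eigenvalue)`, exact for a solid
#' uniform ellipsoid. Derived quantities: normalized axis lengths
#' `(a, b, c) / (a + b + c)` and the two-axis anisotropy `c / (a + c)`.
#'
#' @param volume a [labeled_volume()].
#' @param label cell label (needs at least 27 voxels).
#' @return an `ellipsoid_fit` list: `semi_axes` (a <= b <= c, um), `axes`
#'   (3x3 orthonormal, columns matching `semi_axes`), `center` (um),
#'   `norm_axes`, `two_axis_anisotropy`.
#' @export
fit_ellipsoid <- function(volume, label) {
  pts <- cell_coords(volume, label)
  if (nrow(pts) < 27L)
    stop("cell ", label, " has fewer than 27 voxels; ellipsoid fit refused")
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  cov0 <- crossprod(cc) / nrow(cc)
  if (min(eigen(cov0, symmetric = TRUE, only.values = TRUE)$values) < 1e-9)
    stop("degenerate (coplanar) voxel set for cell ", label)
  # add the within-voxel variance of a uniform cube (side^2/12 per axis) so
  # moments of a voxelized solid match the continuous solid exactly
  covm <- cov0 + diag(volume$voxel_size[c(3, 2, 1)]^2 / 12)
  ev <- eigen(covm, symmetric = TRUE)
  ord <- order(ev$values)                 # ascending: a, b, c
  semi <- sqrt(5 * ev$values[ord])
  axes <- ev$vectors[, ord, drop = FALSE]
  structure(list(semi_axes = semi, axes = axes, center = ctr,
                 norm_axes = semi / sum(semi),
                 two_axis_anisotropy = semi[3] / (semi[1] + semi[3])),
            class = "ellipsoid_fit")
}

#' @exportS3Method base::print
print.ellipsoid_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipsoid_fit> semi-axes (%.3g, %.3g, %.3g) um, anisotropy %.3f\n",
    x$semi_axes[1], x$semi_axes[2], x$semi_axes[3], x$two_axis_anisotropy))
  invisible(x)
}

#' Cell shape descriptors
#'
#' Sphericity `psi = pi^(1/3) (6 V)^(2/3) / A` (1 for a perfect sphere);
#' prolate ellipticity `(c - b) / c` (rugby-ball elongation) and oblate
#' ellipticity `(b - a) / b` (disk flattening) from the fitted semi-axes
#' `a <= b <= c`. Both ellipticities are bounded in [0, 1), zero on a sphere,
#' and monotone in elongation / flattening.
#'
#' @param volume_um3 cell volume, um^3.
#' @param surface_area_um2 cell surface area, um^2.
#' @param fit an `ellipsoid_fit` (or a length-3 vector of semi-axes).
#' @return tibble with `sphericity`, `prolate_ellipticity`,
#'   `oblate_ellipticity`.
#' @export
shape_descriptors <- function(volume_um3, surface_area_um2, fit) {
  stopifnot(volume_um3 > 0, surface_area_um2 > 0)
  semi <- if (inherits(fit, "ellipsoid_fit")) fit$semi_axes else sort(fit)
  tibble::tibble(
    sphericity = pi^(1 / 3) * (6 * volume_um3)^(2 / 3) / surface_area_um2,
    prolate_ellipticity = (semi[3] - semi[2]) / semi[3],
    oblate_ellipticity = (semi[2] - semi[1]) / semi[2]
  )
}

#' Measure all cells of an annotated ovule
#'
#' One row per cell with every size and shape descriptor plus the apical /
#' basal wall areas of the central L2 cell. Per-cell failures (too-small or
#' degenerate cells) are logged and leave NAs; the run continues.
#'
#' @param volume a [labeled_volume()].
#' @param annotation an [annotate_ovule()] result.
#' @param ovule_id identifier written into the table key.
#' @param config a [default_config()].
#' @return a validated cell table ([validate_cell_table()]).
#' @export
measure_cells <- function(volume, annotation, ovule_id = "ovule",
                          config = default_config()) {
  labs <- cell_labels(volume)
  walls <- tryCatch(
    apical_basal_walls(volume, annotation, graph = annotation$graph),
    error = function(e) list(apical_um2 = NA_real_, basal_um2 = NA_real_))
  rows <- lapply(labs, function(l) {
    vol <- measure_volume(volume, l)
    fit <- tryCatch(fit_ellipsoid(volume, l), error = function(e) NULL)
    mes <- tryCatch(
      extract_cell_mesh(volume, l, config$mesh_smoothing_iters,
                        config$mask_smoothing_sigma_vox),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(mes))
      mes <- suppressWarnings(tryCatch(
        extract_cell_mesh(volume, l, 0L, 0.5), error = function(e) NULL))
    area <- if (is.null(mes)) NA_real_ else mes$area_um2
    sh <- if (!is.null(fit) && is.finite(area) && area > 0)
      shape_descriptors(vol, area, fit)
    else tibble::tibble(sphericity = NA_real_,
                        prolate_ellipticity = NA_real_,
                        oblate_ellipticity = NA_real_)
    is_central <- l == annotation$central_l2
    tibble::tibble(
      ovule_id = ovule_id, cell_label = as.integer(l),
      layer = unname(annotation$layers[as.character(l)]),
      contact_class = unname(annotation$contact_class[as.character(l)]),
      volume_um3 = vol,
      semi_axis_a = if (is.null(fit)) NA_real_ else fit$semi_axes[1],
      semi_axis_b = if (is.null(fit)) NA_real_ else fit$semi_axes[2],
      semi_axis_c = if (is.null(fit)) NA_real_ else fit$semi_axes[3],
      norm_axis_a = if (is.null(fit)) NA_real_ else fit$norm_axes[1],
      norm_axis_b = if (is.null(fit)) NA_real_ else fit$norm_axes[2],
      norm_axis_c = if (is.null(fit)) NA_real_ else fit$norm_axes[3],
      two_axis_anisotropy = if (is.null(fit)) NA_real_ else
        fit$two_axis_anisotropy,
      sphericity = sh$sphericity,
      prolate_ellipticity = sh$prolate_ellipticity,
      oblate_ellipticity = sh$oblate_ellipticity,
      surface_area_um2 = area,
      apical_wall_area_um2 = if (is_central) walls$apical_um2 else NA_real_,
      basal_wall_area_um2 = if (is_central) walls$basal_um2 else NA_real_,
      stage = NA_integer_
    )
  })
  validate_cell_table(dplyr::bind_rows(rows))
}
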