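#' Whole-ovule surface mesh from the L1 layer
#'
#' Fuses the L1 cells together with everything they enclose (the full
#' foreground) into one mask and extracts its smoothed iso-surface. Vertices
#' on the base cap (the `base_plane` face, where the crop continues into
#' tissue) are flagged so curvature analysis can exclude them.
#'
#' @param volume a [labeled_volume()].
#' @param layers layer assignment from [assign_layers()].
#' @param smoothing_iters Taubin iterations.
#' @return a [surface_mesh()] with attribute `base_cap`: logical per-vertex
#'   flag for base-plane vertices.
#' @export
ovule_mesh <- function(volume, layers, smoothing_iters = 8L) {
  if (!any(layers == "L1")) stop("no L1 cells assigned")
  mask <- volume$labels > 0L
  mesh <- mask_isosurface(mask, volume$voxel_size, sigma_vox = 0.6,
                          smoothing_iters = smoothing_iters)
  base_cap <- mesh$vertices[, 3] < 1.5 * volume$voxel_size[1]
  attr(mesh, "base_cap") <- base_cap
  mesh
}

#' Principal-axis oriented bounding box of the ovule
#'
#' Bounding box of the fused foreground voxel cloud along its principal
#' axes, box lengths sorted ascending (A <= B <= C). The aspect ratio
#' A / (A + B + C) is the ovule's normalized height: the minimal length A
#' corresponds to the dome height, B and C to the base diameters. A warning
#' is raised when the A axis strays more than 30 degrees from the grid dome
#' axis.
#'
#' @param volume a [labeled_volume()].
#' @param layers layer assignment (L1 must exist).
#' @param axis_aligned use the grid-aligned box instead of the
#'   principal-axis box (for comparison).
#' @return list `lengths` = c(A, B, C) um, `axes` (columns matching the
#'   lengths), `aspect_ratio`.
#' @export
oriented_bounding_box <- function(volume, layers, axis_aligned = FALSE) {
  if (!any(layers == "L1")) stop("no L1 cells assigned")
  idx <- which(volume$labels > 0L, arr.ind = TRUE)
  pts <- voxel_centers(idx, volume$voxel_size)
  if (axis_aligned) {
    axes <- diag(3)
  } else {
    axes <- prcomp(pts, center = TRUE, scale. = FALSE)$rotation
  }
  proj <- sweep(pts, 2, colMeans(pts)) %*% axes
  len <- apply(proj, 2, function(p) diff(range(p))) +
    mean(volume$voxel_size)          # half-voxel support on both sides
  ord <- order(len)
  lengths <- len[ord]
  axes <- axes[, ord, drop = FALSE]
  a_dev <- op_angle(axes[, 1], c(0, 0, 1))
  if (a_dev > 30)
    warning(sprintf(
      "minimal box axis deviates %.0f deg from the dome axis", a_dev))
  list(lengths = lengths, axes = axes,
       aspect_ratio = lengths[1] / sum(lengths))
}

#' Per-vertex mean curvature of a surface mesh
#'
#' Curvature by local tangent-sphere fitting: for each vertex, the
#' neighborhood within `radius` is expressed in a local frame whose z-axis
#' is the outward normal (smallest principal axis of the neighborhood,
#' oriented away from the mesh interior), and the sphere through the vertex
#' tangent to its tangent plane, `x^2 + y^2 + z^2 = 2 R z`, is fitted by
#' least squares: `1/R = 2 sum(z^2) / sum((x^2+y^2+z^2) z)`. Unlike a local
#' quadric, the tangent sphere is unbiased however large the neighborhood
#' cap is — important because the neighborhood radius (40 um, the organ
#' scale) is comparable to dome curvature radii. The sign is positive for a
#' surface bulging toward the outward normal; a locally flat patch
#' (`sum(z^2)` negligible) returns 0. The radius follows the organ scale:
#' `radius` is reduced to `radius_small` (30 um) when the mesh
#' bounding-sphere diameter is below `small_diameter` (80 um), avoiding
#' edge effects on small ovules. Base-cap vertices (attribute `base_cap`)
#' and vertices with fewer than 6 neighbors are masked (NA).
#'
#' @param mesh a [surface_mesh()] (smoothed).
#' @param radius neighborhood radius, um.
#' @param radius_small reduced radius for small meshes, um.
#' @param small_diameter bounding-sphere diameter threshold, um.
#' @return numeric per-vertex mean curvature (um^-1), NA where masked;
#'   attribute `radius_used`.
#' @export
curvature_map <- function(mesh, radius = 40, radius_small = 30,
                          small_diameter = 80) {
  v <- mesh$vertices
  ctr <- colMeans(v)
  diam <- 2 * sqrt(max(rowSums(sweep(v, 2, ctr)^2)))
  r_used <- if (diam < small_diameter) radius_small else radius
  base_cap <- attr(mesh, "base_cap")
  if (is.null(base_cap)) base_cap <- rep(FALSE, nrow(v))
  nv <- nrow(v)
  out <- rep(NA_real_, nv)
  # neighborhoods are drawn from a strided pool of surface vertices (the
  # fit needs a spread sample, not every vertex) that excludes base-cap
  # vertices, so the artificial cap never enters a fit
  eligible <- which(!base_cap)
  if (length(eligible) < 6L) return(out)
  pool <- eligible[seq(1L, length(eligible),
                       by = max(1L, length(eligible) %/% 4000L))]
  vp <- v[pool, , drop = FALSE]
  cell <- r_used
  keyf <- function(p) paste(floor(p[, 1] / cell), floor(p[, 2] / cell),
                            floor(p[, 3] / cell))
  buckets <- split(seq_len(nrow(vp)), keyf(vp))
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (b in seq_along(buckets))
    assign(names(buckets)[b], buckets[[b]], envir = lookup)
  neigh_of <- function(p) {
    ks <- as.vector(outer(outer(
      paste(floor(p[1] / cell) + (-1:1)),
      paste(floor(p[2] / cell) + (-1:1)), paste),
      paste(floor(p[3] / cell) + (-1:1)), paste))
    unlist(lapply(ks, function(k)
      if (exists(k, envir = lookup, inherits = FALSE))
        get(k, envir = lookup) else NULL), use.names = FALSE)
  }
  interior_ctr <- ctr
  for (i in seq_len(nv)) {
    if (base_cap[i]) next
    cand <- neigh_of(v[i, ])
    d2 <- rowSums(sweep(vp[cand, , drop = FALSE], 2, v[i, ])^2)
    nb <- cand[d2 <= r_used^2]
    if (length(nb) < 6L) next
    if (length(nb) > 80L)      # a spread subsample is enough for the fit
      nb <- nb[seq(1L, length(nb), length.out = 80L)]
    pts <- vp[nb, , drop = FALSE]
    mu <- colMeans(pts)
    ev <- eigen(stats::cov(sweep(pts, 2, mu)), symmetric = TRUE)
    nrm <- ev$vectors[, which.min(ev$values)]
    # orient outward (away from the mesh interior)
    if (sum(nrm * (v[i, ] - interior_ctr)) < 0) nrm <- -nrm
    loc <- sweep(pts, 2, v[i, ])
    lz <- as.vector(loc %*% nrm)
    rho <- rowSums(loc^2)
    denom <- sum(rho * lz)
    numer <- 2 * sum(lz^2)
    # flat patch: height deviations are a vanishing fraction of the
    # neighborhood extent, below the curvature the fit could resolve
    if (mean(abs(lz)) < 0.02 * sqrt(mean(rho)) || abs(denom) < 1e-12) {
      out[i] <- 0
      next
    }
    # tangent sphere x^2+y^2+z^2 = 2 R z; neighbors of an outward-bulging
    # surface lie at z < 0 in the outward frame, so flip the sign to make
    # domes positive
    out[i] <- -numer / denom
  }
  attr(out, "radius_used") <- r_used
  out
}

#' Correlate central-cell anisotropy with ovule shape
#'
#' Pairs each ovule's central L2 normalized major axis length with its
#' aspect ratio and computes the Spearman rank correlation, with a
#' two-sided permutation p-value (exact enumeration up to n = 7, otherwise
#' seeded Monte Carlo with at least 10,000 permutations).
#'
#' @param pairs data frame with columns `cell_anisotropy` (central L2
#'   normalized major axis) and `ovule_aspect` (A / (A+B+C)), one row per
#'   ovule.
#' @param n_permutations Monte Carlo permutation count.
#' @param seed RNG seed for the Monte Carlo path.
#' @return one-row tibble: `rho`, `p_value`, `n`, `method`.
#' @export
correlate_cell_organ_shape <- function(pairs, n_permutations = 10000L,
                                       seed = 1L) {
  x <- pairs$cell_anisotropy
  y <- pairs$ovule_aspect
  n <- length(x)
  if (n < 3L) stop("need at least 3 ovules")
  rho_obs <- cor(x, y, method = "spearman")
  rho_perm <- function(perm) cor(x, y[perm], method = "spearman")
  if (n <= 7L) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, rho_perm)
    p <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
    method <- "exact permutation"
  } else {
    p <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_permutations))
        if (abs(rho_perm(sample.int(n))) >= abs(rho_obs) - 1e-12)
          hits <- hits + 1L
      (hits + 1) / (n_permutations + 1)
    })
    method <- "Monte Carlo permutation"
  }
  tibble::tibble(rho = rho_obs, p_value = p, n = n, method = method)
}

# all permutations of 1..n (n small)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    m <- sub
    m[m >= i] <- m[m >= i] + 1L
    unname(cbind(i, m))
  }))
}
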