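# ---------------------------------------------------------------------------
# Synthetic ovule generator: labeled dome tissues with known ground truth
# (layers, central cells, stages, planted divisions). The tessellation is an
# additively weighted nearest-seed (power-diagram-like) assignment on the
# voxel grid, which guarantees that every foreground voxel belongs to
# exactly one cell.
# ---------------------------------------------------------------------------

# squared weighted anisotropic distance from voxels to one seed;
# axial_ratio < 1 cheapens the axial direction, elongating the cell along u
seed_dist2 <- function(coords, seed, weight = 0, axial_ratio = 1,
                       u = c(0, 0, 1)) {
  dxyz <- sweep(coords, 2, seed)
  ax <- dxyz %*% u
  r2 <- rowSums(dxyz^2)
  as.vector(axial_ratio * ax^2 + (r2 - ax^2)) - weight
}

#' Generate a labeled dome tessellation with ground truth
#'
#' Voxelizes a superellipsoid dome
#' `(x/Rx)^2 + (y/Ry)^2 + (z/H)^n <= 1, z >= 0` sitting on the base plane,
#' splits the foreground into depth bands (one per cell layer), places seeds
#' on each band (well-spread via k-means on the band voxels), puts exactly
#' one L2 seed on the dome axis, and assigns every foreground voxel to its
#' nearest seed under an additively weighted metric. The central seed's
#' weight is tuned by bisection so its cell volume hits
#' `central_l2_target_volume`; its metric can be made axially anisotropic to
#' elongate the cell along the dome axis (the archesporial/MMC shape).
#'
#' @param H dome height, um.
#' @param Rx,Ry dome base radii, um.
#' @param squareness superellipsoid exponent n (2 = ellipsoidal dome; larger
#'   values square the dome).
#' @param layer_thicknesses depths of the L1..L3 bands, um (rest is L4).
#' @param seeds_per_layer number of cells per layer band (length 4: L1..L4).
#' @param central_l2_target_volume target central cell volume, um^3.
#' @param voxel_size `(dz, dy, dx)` um.
#' @param rng_seed integer seed; identical seeds give identical volumes.
#' @param central_axial_ratio metric ratio (< 1 elongates the central cell
#'   along the dome axis).
#' @param central_max_radius hard cap (um) on the central cell's lateral
#'   radius about the dome axis; together with the target volume this
#'   controls its slenderness (columnar vs round).
#' @param stack_seed also place an on-axis L3 (stack) seed directly beneath
#'   the central cell — the configuration of an organ whose archesporial
#'   division happened long ago (the stack cell exists, with no wall
#'   continuity).
#' @param volume_tol accept the tuned central volume within this relative
#'   tolerance (default 0.15).
#' @return list `volume` (a [labeled_volume()]) and `truth` (an
#'   `ovule_truth`: `cells` tibble with per-cell layer, contact class and
#'   division fields; `meta` with dome parameters and the central label).
#' @export
generate_dome_tessellation <- function(H, Rx, Ry, squareness = 2,
                                       layer_thicknesses = c(5, 7, 7),
                                       seeds_per_layer = c(30, 12, 8, 6),
                                       central_l2_target_volume = 500,
                                       voxel_size = c(1, 1, 1),
                                       rng_seed = 1L,
                                       central_axial_ratio = 1,
                                       central_max_radius = Inf,
                                       stack_seed = FALSE,
                                       volume_tol = 0.15) {
  stopifnot(H > 0, Rx > 0, Ry > 0, sum(layer_thicknesses) < H)
  vs <- voxel_size
  margin <- 2
  nx <- ceiling((2 * Rx + 2 * margin) / vs[3])
  ny <- ceiling((2 * Ry + 2 * margin) / vs[2])
  nz <- ceiling((H + margin) / vs[1])
  cx <- Rx + margin; cy <- Ry + margin      # dome axis position
  xs <- (seq_len(nx) - 0.5) * vs[3] - cx
  ys <- (seq_len(ny) - 0.5) * vs[2] - cy
  zs <- (seq_len(nz) - 0.5) * vs[1]
  # dome mask (z measured from the base plane)
  fx <- (xs / Rx)^2
  fy <- (ys / Ry)^2
  fz <- (zs / H)^squareness
  g <- outer(outer(fz, fy, "+"), fx, "+")   # dim (nz, ny, nx)
  mask <- g <= 1
  if (!any(mask)) stop("empty dome: check H, Rx, Ry")
  vol1 <- labeled_volume(array(as.integer(mask), dim(mask)), vs)
  depth <- sqrt(exterior_distance(vol1))
  t1 <- layer_thicknesses[1]
  t2 <- layer_thicknesses[2]
  t3 <- layer_thicknesses[3]
  band <- array(4L, dim(mask))
  band[depth <= t1] <- 1L
  band[depth > t1 & depth <= t1 + t2] <- 2L
  band[depth > t1 + t2 & depth <= t1 + t2 + t3] <- 3L
  band[!mask] <- 0L

  idx_all <- which(mask, arr.ind = TRUE)
  coords_all <- voxel_centers(idx_all, vs)
  band_fg <- band[mask]

  # seeds on concentric offset shells: well-spread points on the exterior
  # surface, pushed inward along the local normal to each band's midpoint
  # depth (L4 seeds are spread over the deep interior instead)
  depth_s <- smooth_field(depth, 1)
  inward_at <- function(p) {
    dgrid <- dim(depth_s)
    i <- min(max(ceiling(p[1] / vs[3]), 2L), dgrid[3] - 1L)
    j <- min(max(ceiling(p[2] / vs[2]), 2L), dgrid[2] - 1L)
    k <- min(max(ceiling(p[3] / vs[1]), 2L), dgrid[1] - 1L)
    g3 <- c(depth_s[k, j, i + 1] - depth_s[k, j, i - 1],
            depth_s[k, j + 1, i] - depth_s[k, j - 1, i],
            depth_s[k + 1, j, i] - depth_s[k - 1, j, i]) /
      (2 * vs[c(3, 2, 1)])
    nn <- sqrt(sum(g3^2))
    if (nn < 1e-9) c(0, 0, -1) else g3 / nn
  }
  surf_pts <- coords_all[depth[mask] <= max(vs), , drop = FALSE]
  band_mid <- c(t1 / 2, t1 + t2 / 2, t1 + t2 + t3 / 2)
  seeds <- NULL
  seed_layer <- integer()
  with_seed(rng_seed, {
    for (lay in 1:3) {
      k <- seeds_per_layer[lay]
      if (k == 0L) next
      k <- min(k, nrow(surf_pts))
      ctrs <- if (k == 1L) matrix(colMeans(surf_pts), 1) else
        suppressWarnings(kmeans(surf_pts, k, iter.max = 25L,
                                nstart = 1L)$centers)
      sl <- t(apply(ctrs, 1, function(p) p + band_mid[lay] * inward_at(p)))
      seeds <- rbind(seeds, sl)
      seed_layer <- c(seed_layer, rep(lay, nrow(sl)))
    }
    deep <- coords_all[band_fg == 4L, , drop = FALSE]
    k4 <- min(seeds_per_layer[4], nrow(deep))
    if (k4 > 0L && nrow(deep) > 0L) {
      ctrs <- if (k4 == 1L) matrix(colMeans(deep), 1) else
        suppressWarnings(kmeans(deep, k4, iter.max = 25L,
                                nstart = 1L)$centers)
      seeds <- rbind(seeds, ctrs)
      seed_layer <- c(seed_layer, rep(4L, nrow(ctrs)))
    }
  })
  # the unique on-axis L2 seed: apex depth-band midpoint on the dome axis
  # (grid coordinates: the axis passes through (cx, cy))
  central_seed <- c(cx, cy, H - (t1 + t2 / 2))
  l2 <- which(seed_layer == 2L)
  if (length(l2) == 0L) stop("need at least one L2 seed")
  d_ax <- sqrt(rowSums(sweep(seeds[l2, , drop = FALSE], 2, central_seed)^2))
  central_idx <- l2[which.min(d_ax)]
  seeds[central_idx, ] <- central_seed
  stack_idx <- NA_integer_
  if (stack_seed) {
    # a near-axis L3 (stack) seed directly beneath the central cell: an
    # organ whose archesporial division lies far in the past — the stack
    # cell exists but its walls show no continuity with the central cell.
    # A small lateral jog desynchronizes its side walls from the central
    # cell's (perfectly coaxial cells would be artificially continuous).
    jog <- with_seed(rng_seed + 7L, {
      th <- runif(1, 0, 2 * pi)
      r <- runif(1, 1.5, 3)
      c(r * cos(th), r * sin(th), 0)
    })
    stack_pos <- c(cx, cy, H - (t1 + t2 + t3 / 2)) + jog
    l3 <- which(seed_layer == 3L)
    if (length(l3) == 0L) stop("stack seed requires L3 seeds")
    d3 <- sqrt(rowSums(sweep(seeds[l3, , drop = FALSE], 2, stack_pos)^2))
    stack_idx <- l3[which.min(d3)]
    seeds[stack_idx, ] <- stack_pos
  }

  ns <- nrow(seeds)
  # distances: central seed gets the anisotropic weighted metric. The
  # epidermis is a clean sheet: L1-band voxels are contested among L1 seeds
  # only and deeper voxels among deeper seeds only (L1 maintains itself by
  # anticlinal divisions and never dips below its band).
  depth_fg_all <- depth[mask]
  in_l1_band <- depth_fg_all <= layer_thicknesses[1]
  dmin <- rep(Inf, nrow(coords_all))
  amin <- integer(nrow(coords_all))
  for (s in seq_len(ns)) {
    if (s == central_idx) next
    ds <- seed_dist2(coords_all, seeds[s, ])
    eligible <- if (seed_layer[s] == 1L) in_l1_band else !in_l1_band
    if (!is.na(stack_idx) && s == stack_idx &&
        is.finite(central_max_radius)) {
      # the stack cell is narrower than the central cell above it, so its
      # side walls sit radially inset from the central cell's — an old
      # division leaves no flush wall continuation
      lat2_s <- (coords_all[, 1] - seeds[s, 1])^2 +
        (coords_all[, 2] - seeds[s, 2])^2
      eligible <- eligible & lat2_s < (0.8 * central_max_radius)^2
    }
    upd <- eligible & ds < dmin
    dmin[upd] <- ds[upd]
    amin[upd] <- s
  }
  dc <- seed_dist2(coords_all, seeds[central_idx, ],
                   axial_ratio = central_axial_ratio)
  # bisection on the central weight to reach the target volume; the central
  # cell is hypodermal by construction and never breaches the L1 band
  vv <- prod(vs)
  target_n <- central_l2_target_volume / vv
  depth_fg <- depth_fg_all
  allowed <- depth_fg > t1
  if (is.finite(central_max_radius)) {
    lat2 <- (coords_all[, 1] - cx)^2 + (coords_all[, 2] - cy)^2
    allowed <- allowed & lat2 < central_max_radius^2
  }
  if (!is.na(stack_idx)) {
    # the stack cell is the central cell's basal neighbor: the central cell
    # may neither swallow the stack's core nor plunge past it (its basal
    # wall rests on the stack)
    allowed <- allowed &
      seed_dist2(coords_all, seeds[stack_idx, ]) > (t3 / 2)^2 &
      coords_all[, 3] > seeds[stack_idx, 3] + t3 / 4
  }
  gap <- dc - dmin                      # cell = { gap < w } & allowed
  lo <- 0; hi <- max(gap[is.finite(gap)]) + 1
  if (sum(gap < lo & allowed) > target_n) lo <- min(gap) - 1
  for (it in seq_len(40L)) {
    mid <- (lo + hi) / 2
    if (sum(gap < mid & allowed) < target_n) lo <- mid else hi <- mid
  }
  w <- hi
  attained <- sum(gap < w & allowed) * vv
  if (abs(attained - central_l2_target_volume) >
      volume_tol * central_l2_target_volume)
    stop(sprintf(
      "central cell volume infeasible: target %.4g um^3, attained %.4g um^3",
      central_l2_target_volume, attained))
  lab_fg <- amin
  lab_fg[gap < w & allowed] <- central_idx

  labels <- array(0L, dim(mask))
  labels[mask] <- lab_fg
  volume <- labeled_volume(labels, vs)
  volume <- cleanup_fragments(volume, sort(unique(lab_fg)))
  lab_fg <- volume$labels[mask]

  present <- sort(unique(lab_fg))
  present <- present[present > 0L]
  graph <- build_adjacency(volume, min_contact_area = 0)
  classes <- assign_contact_degrees(graph, central_idx)
  # true layer = depth band actually occupied (centroid depth); the central
  # cell is hypodermal (L2) by construction whatever its extent
  centroid_band <- vapply(present, function(l) {
    sel <- lab_fg == l
    dep <- mean(depth_fg[sel])
    min(findInterval(dep, cumsum(c(t1, t2, t3))) + 1L, 4L)
  }, integer(1))
  centroid_band[present == central_idx] <- 2L
  cells <- tibble::tibble(
    cell_label = present,
    layer = paste0("L", centroid_band),
    contact_class = unname(classes[as.character(present)]),
    divided = FALSE, orientation = NA_character_,
    plane_nx = NA_real_, plane_ny = NA_real_, plane_nz = NA_real_,
    offset_fraction = NA_real_, jitter_um = NA_real_,
    sibling = NA_integer_)
  cells$contact_class[cells$cell_label == central_idx] <- "central_L2"
  if (!is.na(stack_idx) && stack_idx %in% present)
    cells$contact_class[cells$cell_label == stack_idx] <- "central_L3"
  truth <- structure(list(
    cells = cells,
    meta = list(H = H, Rx = Rx, Ry = Ry, squareness = squareness,
                layer_thicknesses = layer_thicknesses,
                central_label = central_idx,
                central_l3_label = if (!is.na(stack_idx) &&
                                       stack_idx %in% present) stack_idx
                else NA_integer_,
                stage = NA_integer_, rng_seed = rng_seed,
                central_axial_ratio = central_axial_ratio,
                attained_central_volume = attained)),
    class = "ovule_truth")
  list(volume = volume, truth = truth)
}

#' @exportS3Method base::print
print.ovule_truth <- function(x, ...) {
  cat(sprintf(
    "<ovule_truth> %d cells, dome H=%.3g Rx=%.3g Ry=%.3g um, central = %d\n",
    nrow(x$cells), x$meta$H, x$meta$Rx, x$meta$Ry, x$meta$central_label))
  invisible(x)
}

#' Plant a cell division into a labeled volume
#'
#' Splits one cell by a plane through the point dividing its extent along
#' the plane normal at fraction `f` (basal/negative side keeps a new label).
#' The normal follows the requested orientation relative to the local radial
#' (outward surface-normal) direction at the cell centroid: periclinal =
#' radial, anticlinal = perpendicular to radial, oblique = 45 degrees. With
#' `jitter > 0`, each daughter's non-shared walls are displaced
#' independently (each daughter grows into each non-sibling neighbor by its
#' own random amount of scale `jitter`), emulating the independent growth of
#' daughters that breaks wall continuity in older divisions; `jitter = 0`
#' leaves the daughters' free walls exactly coplanar with the mother's.
#'
#' @param volume a [labeled_volume()].
#' @param truth the matching `ovule_truth`.
#' @param cell_label cell to split.
#' @param orientation `"periclinal"`, `"anticlinal"` or `"oblique"`.
#' @param f extent fraction of the split plane (0.5 = mid-plane).
#' @param jitter wall displacement scale, um (0 = perfect continuity).
#' @param rng_seed integer seed for jitter and the anticlinal azimuth.
#' @return list `volume`, `truth` (both updated), `labels` = c(apical,
#'   basal) daughter labels.
#' @export
plant_division <- function(volume, truth, cell_label,
                           orientation = c("periclinal", "anticlinal",
                                           "oblique"),
                           f = 0.5, jitter = 0, rng_seed = 1L) {
  orientation <- match.arg(orientation)
  stopifnot(f > 0, f < 1)
  idx <- label_indices(volume, cell_label)
  if (nrow(idx) == 0L) stop("cell ", cell_label, " not present")
  coords <- voxel_centers(idx, volume$voxel_size)
  ctr <- colMeans(coords)
  dist2 <- exterior_distance(volume)
  u <- radial_direction(dist2, volume$voxel_size, ctr)
  nrm <- with_seed(rng_seed, {
    perp <- random_perpendicular(u)
    switch(orientation,
           periclinal = u,
           anticlinal = perp,
           oblique = (u + perp) / sqrt(2))
  })
  nrm <- nrm / sqrt(sum(nrm^2))
  if (orientation == "periclinal") {
    # periclinal walls are parallel to the organ surface: in a curved dome
    # this is the depth iso-surface, not a flat plane (a plane would wrap
    # the basal daughter onto the flank and give it apical contacts)
    kji <- idx
    dep <- sqrt(dist2[kji])
    s <- -dep                      # larger = more apical
    thr <- min(s) + f * (max(s) - min(s))
    apical_side <- s > thr
  } else {
    s <- as.vector(sweep(coords, 2, ctr) %*% nrm)
    thr <- min(s) + f * (max(s) - min(s))
    # apical daughter = the side the outward normal points to
    apical_side <- s > thr
    if (sum(nrm * u) < 0) apical_side <- !apical_side
  }
  n_ap <- sum(apical_side); n_ba <- sum(!apical_side)
  if (min(n_ap, n_ba) < 27L)
    stop("degenerate split: daughter of ", min(n_ap, n_ba), " voxels")
  new_label <- max(cell_labels(volume)) + 1L
  labels <- volume$labels
  basal_idx <- idx[!apical_side, , drop = FALSE]
  labels[cbind(basal_idx)] <- new_label
  vol2 <- labeled_volume(labels, volume$voxel_size, volume$base_plane)
  vol2 <- cleanup_fragments(vol2, c(cell_label, new_label))

  daughters <- c(apical = cell_label, basal = new_label)
  if (jitter > 0) {
    vol2 <- with_seed(rng_seed + 1L, {
      v <- vol2
      g0 <- build_adjacency(v, min_contact_area = 0, keep_faces = FALSE)
      # deform only the walls flanking the junction (neighbors adjacent to
      # both daughters): those carry the continuity signal, and the apical
      # and basal caps keep the planted cell volumes clean
      nbs_all <- setdiff(intersect(cell_neighbors(g0, daughters[1]),
                                   cell_neighbors(g0, daughters[2])),
                         daughters)
      # opposite tilt signs for the two daughters at every shared side:
      # their wall ends step apart at the junction
      signs <- setNames(sample(c(-1, 1), length(nbs_all), replace = TRUE),
                        nbs_all)
      v <- jitter_free_walls(v, daughters[1], daughters[2], jitter, signs)
      v <- jitter_free_walls(v, daughters[2], daughters[1], jitter, -signs)
      cleanup_fragments(v, c(daughters, nbs_all))
    })
  }
  # truth bookkeeping: daughters inherit, layers re-derived from depth bands
  cells <- truth$cells
  mother_row <- cells[cells$cell_label == cell_label, ]
  lt <- truth$meta$layer_thicknesses
  layer_of <- function(lbl) {
    dctr <- colMeans(cell_coords(vol2, lbl))
    dep <- sqrt(interp_field(dist2, volume$voxel_size, dctr))
    paste0("L", min(findInterval(dep, cumsum(lt)) + 1L, 4L))
  }
  newrow <- mother_row
  newrow$cell_label <- new_label
  cells <- dplyr::bind_rows(cells, newrow)
  for (lbl in daughters) {
    i <- which(cells$cell_label == lbl)
    cells$divided[i] <- TRUE
    cells$orientation[i] <- orientation
    cells$plane_nx[i] <- nrm[1]; cells$plane_ny[i] <- nrm[2]
    cells$plane_nz[i] <- nrm[3]
    cells$offset_fraction[i] <- f
    cells$jitter_um[i] <- jitter
    cells$sibling[i] <- unname(setdiff(daughters, lbl))
    cells$layer[i] <- layer_of(lbl)
  }
  if (cell_label == truth$meta$central_label) {
    cells$contact_class[cells$cell_label == new_label] <- "central_L3"
    truth$meta$central_l3_label <- new_label
  }
  truth$cells <- cells
  list(volume = vol2, truth = truth,
       labels = c(apical = unname(cell_label), basal = new_label))
}

# a reproducible random unit vector perpendicular to u
random_perpendicular <- function(u) {
  repeat {
    v <- rnorm(3)
    v <- v - sum(v * u) * u
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

# Deform daughter `d`'s free walls: each wall with a non-sibling neighbor X
# is tilted about its own mid-line — the daughter grows into X on one half
# of the wall and recedes on the other half (signed displacement
# a * (h - 1/2), h = normalized position along the daughter's own axis away
# from the sibling). The tilt is approximately volume-neutral, so planted
# cell volumes survive, while the wall ends at the sibling junction are
# displaced independently for the two daughters, breaking wall continuity
# the way independent daughter growth does.
jitter_free_walls <- function(volume, d, sibling, jitter, signs = NULL) {
  g <- build_adjacency(volume, min_contact_area = 0, keep_faces = FALSE)
  nbs <- setdiff(cell_neighbors(g, d, include_exterior = FALSE), sibling)
  if (!is.null(signs)) nbs <- intersect(nbs, as.integer(names(signs)))
  if (length(nbs) == 0L) return(volume)
  lab <- volume$labels
  vs <- volume$voxel_size
  ctr_d <- colMeans(cell_coords(volume, d))
  ctr_s <- colMeans(cell_coords(volume, sibling))
  m <- ctr_d - ctr_s
  m <- m / sqrt(sum(m^2))            # away from the sibling
  sd_own <- as.vector(cell_coords(volume, d) %*% m)
  smin <- min(sd_own); smax <- max(sd_own)
  marg <- ceiling(jitter / min(vs)) + 2L
  dall <- dim(lab)
  for (X in nbs) {
    a <- jitter * runif(1, 0.7, 1.1)
    sgn <- if (!is.null(signs) && as.character(X) %in% names(signs))
      signs[[as.character(X)]] else sample(c(-1, 1), 1)
    idx_dx <- which(lab == d | lab == X, arr.ind = TRUE)
    lo <- pmax(apply(idx_dx, 2, min) - marg, 1L)
    hi <- pmin(apply(idx_dx, 2, max) + marg, dall)
    sub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    d2d <- edt3d(array(sub == d, dim(sub)), vs)
    d2x <- edt3d(array(sub == X, dim(sub)), vs)
    idx_sub <- which(sub == d | sub == X, arr.ind = TRUE)
    glob <- sweep(idx_sub, 2, lo - 1L, "+")
    px <- voxel_centers(glob, vs)
    h <- pmin(pmax((as.vector(px %*% m) - smin) / max(smax - smin, 1e-9),
                   0), 1)
    delta <- sgn * a * (h - 0.5)
    is_x <- sub[idx_sub] == X
    take <- is_x & delta > 0 & d2d[idx_sub] <= delta^2         # d grows
    give <- !is_x & delta < 0 & d2x[idx_sub] <= delta^2        # d recedes
    if (any(take)) sub[idx_sub[take, , drop = FALSE]] <- d
    if (any(give)) sub[idx_sub[give, , drop = FALSE]] <- X
    lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  }
  labeled_volume(lab, vs, volume$base_plane)
}

#' Default per-stage cohort parameters
#'
#' The study conditions of the synthetic cohort: four developmental stages
#' with central-cell volume means doubling per stage (500, 1000, 2000,
#' 4000 um^3, log-normal with 10% scatter), dome size and aspect growing
#' with stage, central-cell axial elongation growing with stage (coupled
#' anisotropy), a recent central periclinal division (Type 2: continuous
#' walls) in 70% / 42% of Stage 1 / 2 organs — other organs carry a
#' separate stack cell with no wall continuity (Type 1: the archesporial
#' division lies in the past and independent growth has erased the
#' signature) — and two recent periclinal neighbor divisions per organ.
#'
#' @param n_ovules organs per stage (length 1 or 4).
#' @return tibble with one row per stage.
#' @export
default_stage_params <- function(n_ovules = 10L) {
  if (length(n_ovules) == 1L) n_ovules <- rep(n_ovules, 4L)
  tibble::tibble(
    stage = 1:4,
    n_ovules = as.integer(n_ovules),
    central_volume_mean = c(500, 1000, 2000, 4000),
    central_volume_sdlog = 0.1,
    H = c(30, 38, 46, 54),
    Rx = c(22, 24, 26, 28),
    Ry = c(22, 24, 26, 28),
    squareness = c(3.2, 2.8, 2.4, 2.1),
    layer_t1 = c(5, 5, 6, 6),
    layer_t2 = c(7, 12, 19, 26),
    layer_t3 = c(7, 8, 9, 9),
    seeds_l1 = c(30, 38, 46, 54),
    seeds_l2 = c(12, 14, 22, 26),
    seeds_l3 = c(8, 9, 11, 13),
    seeds_l4 = c(5, 6, 8, 10),
    central_axial_ratio = c(0.7, 0.55, 0.4, 0.3),
    central_slenderness = c(0.8, 1.1, 1.4, 1.7),
    type2_fraction = c(0.7, 0.42, 0, 0),
    symmetric_ratio_fraction = 0.6,
    n_recent_neighbor_divisions = 2L
  )
}

#' Generate a synthetic ovule cohort
#'
#' Draws per-organ central-cell volumes log-normally around the stage means,
#' generates each dome, and executes the division plan. With the stage's
#' `type2_fraction` probability the organ is Type 2: its archesporial cell
#' is split periclinally into the central L2 (MMC) and central L3 (stack)
#' daughters with perfect wall continuity, at a planted daughter volume
#' ratio drawn from a symmetric (mean 1.0) or asymmetric (mean 2.3) class.
#' Otherwise the organ is Type 1: the stack cell is generated as a separate
#' on-axis cell with ordinary (discontinuous) walls, the configuration left
#' once independent growth has erased an old division's signature. Neighbor
#' L2 cells additionally receive recent (continuous) periclinal divisions.
#'
#' @param stage_params per-stage plan, as from [default_stage_params()].
#' @param rng_seed master integer seed; every stochastic draw derives from
#'   it.
#' @param voxel_size `(dz, dy, dx)` um.
#' @param couple_anisotropy keep the stage-coupled central elongation and
#'   dome aspect (`TRUE`, the default study condition) or draw both
#'   independently at random (`FALSE`, the null condition for the cell-organ
#'   shape correlation).
#' @return list of ovules, each `list(volume, truth)`; names `ovule_<i>`.
#' @export
generate_cohort <- function(stage_params = default_stage_params(),
                            rng_seed = 1L, voxel_size = c(1, 1, 1),
                            couple_anisotropy = TRUE) {
  ovules <- list()
  counter <- 0L
  for (si in seq_len(nrow(stage_params))) {
    sp <- stage_params[si, ]
    if (sp$n_ovules == 0L) next
    for (oi in seq_len(sp$n_ovules)) {
      counter <- counter + 1L
      seed_i <- (rng_seed * 1000L + counter * 13L) %% .Machine$integer.max
      ov <- with_seed(seed_i, {
        lv <- rnorm(1, log(sp$central_volume_mean), sp$central_volume_sdlog)
        # winsorize at 1.5 sd: within-stage volumes stay in their band
        lv <- min(max(lv, log(sp$central_volume_mean) -
                        1.5 * sp$central_volume_sdlog),
                  log(sp$central_volume_mean) + 1.5 * sp$central_volume_sdlog)
        v_central <- exp(lv)
        is_type2 <- runif(1) < sp$type2_fraction
        sym <- runif(1) < sp$symmetric_ratio_fraction
        ratio <- if (sym) max(rnorm(1, 1.0, 0.05), 1.0)
        else rnorm(1, 2.3, 0.1)
        axr <- sp$central_axial_ratio
        slender <- sp$central_slenderness
        Hm <- 1
        if (!couple_anisotropy) {
          # null condition: the drivers of cell elongation (slenderness,
          # axial metric) and of organ aspect (dome height) are drawn
          # independently instead of following the stage
          axr <- runif(1, 0.3, 0.7)
          slender <- runif(1, 0.8, 1.7)
          Hm <- runif(1, 0.8, 1.2)
        }
        list(v_central = v_central, is_type2 = is_type2, ratio = ratio,
             axial_ratio = axr, slenderness = slender, H_mult = Hm)
      })
      v_basal <- ov$v_central / ov$ratio
      v_arch <- if (ov$is_type2) ov$v_central + v_basal else ov$v_central
      # slenderness h/(2r) plus volume fix the central cell's column radius
      r_max <- 1.08 * (v_arch / (2 * pi * ov$slenderness))^(1 / 3)
      gen <- generate_dome_tessellation(
        H = sp$H * ov$H_mult, Rx = sp$Rx, Ry = sp$Ry,
        squareness = sp$squareness,
        layer_thicknesses = c(sp$layer_t1, sp$layer_t2, sp$layer_t3),
        seeds_per_layer = c(sp$seeds_l1, sp$seeds_l2, sp$seeds_l3,
                            sp$seeds_l4),
        central_l2_target_volume = v_arch,
        voxel_size = voxel_size, rng_seed = seed_i,
        central_axial_ratio = ov$axial_ratio,
        central_max_radius = r_max,
        stack_seed = !ov$is_type2)
      vol <- gen$volume; truth <- gen$truth
      if (ov$is_type2) {
        # recent central periclinal division: split the archesporial cell
        # at the planted basal volume fraction, walls left continuous
        f_split <- split_fraction_for_volume(vol, truth$meta$central_label,
                                             v_basal / v_arch)
        pd <- plant_division(vol, truth, truth$meta$central_label,
                             "periclinal", f = f_split, jitter = 0,
                             rng_seed = seed_i + 1L)
        vol <- pd$volume; truth <- pd$truth
      }
      # recent periclinal neighbor divisions
      plan <- rep(0, sp$n_recent_neighbor_divisions)
      cand <- truth$cells$cell_label[
        truth$cells$layer == "L2" & !truth$cells$divided &
          truth$cells$contact_class %in% c("contact1", "contact2")]
      cand <- with_seed(seed_i + 2L,
                        sample(cand, min(length(plan), length(cand))))
      for (ci in seq_along(cand)) {
        pd <- tryCatch(
          plant_division(vol, truth, cand[ci], "periclinal", f = 0.5,
                         jitter = plan[ci], rng_seed = seed_i + 2L + ci),
          error = function(e) NULL)
        if (!is.null(pd)) { vol <- pd$volume; truth <- pd$truth }
      }
      truth <- refresh_truth_contacts(vol, truth)
      truth$meta$stage <- sp$stage
      truth$meta$planted_type2 <- ov$is_type2
      truth$meta$planted_ratio <- ov$ratio
      truth$meta$planted_central_volume <- ov$v_central
      ovules[[sprintf("ovule_%03d", counter)]] <-
        list(volume = vol, truth = truth)
    }
  }
  ovules
}

# Reabsorb disconnected fragments that voxel reassignment can leave behind:
# every cell keeps its largest 6-connected component; stray fragment voxels
# are relabeled to their majority 6-neighbor, layer by layer.
cleanup_fragments <- function(volume, labels_to_check) {
  lab <- volume$labels
  d <- dim(lab)
  for (l in labels_to_check) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    lo <- pmax(apply(idx, 2, min) - 1L, 1L)
    hi <- pmin(apply(idx, 2, max) + 1L, d)
    sub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    comp <- mask_components(array(sub == l, dim(sub)))
    if (max(comp) <= 1L) next
    keep <- which.max(tabulate(comp[comp > 0L]))
    stray <- comp > 0L & comp != keep
    guard <- 0L
    while (any(stray) && guard < 50L) {
      guard <- guard + 1L
      sidx <- which(stray, arr.ind = TRUE)
      for (q in seq_len(nrow(sidx))) {
        k <- sidx[q, 1]; j <- sidx[q, 2]; i <- sidx[q, 3]
        nb <- c(if (k > 1) sub[k - 1, j, i], if (k < dim(sub)[1]) sub[k + 1, j, i],
                if (j > 1) sub[k, j - 1, i], if (j < dim(sub)[2]) sub[k, j + 1, i],
                if (i > 1) sub[k, j, i - 1], if (i < dim(sub)[3]) sub[k, j, i + 1])
        nb <- nb[nb != l & nb != 0L]
        if (length(nb)) {
          sub[k, j, i] <- as.integer(names(sort(table(nb),
                                                decreasing = TRUE))[1])
          stray[k, j, i] <- FALSE
        }
      }
    }
    if (any(stray)) {   # isolated in background: make background
      sub[stray] <- 0L
    }
    lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  }
  labeled_volume(lab, volume$voxel_size, volume$base_plane)
}

# connected-component labeling of a 3D logical mask (6-connectivity)
mask_components <- function(mask) {
  dsub <- dim(mask)
  lin <- which(mask)
  out <- array(0L, dsub)
  if (length(lin) == 0L) return(out)
  id <- array(0L, dsub)
  id[lin] <- seq_along(lin)
  arr <- which(mask, arr.ind = TRUE)
  edges <- list()
  for (ax in 1:3) {
    nb <- arr
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= dsub[ax]
    ok[ok] <- mask[nb[ok, , drop = FALSE]]
    if (any(ok))
      edges[[ax]] <- cbind(id[arr[ok, , drop = FALSE]],
                           id[nb[ok, , drop = FALSE]])
  }
  em <- do.call(rbind, edges)
  if (is.null(em)) {
    out[lin] <- seq_along(lin)
    return(out)
  }
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(lin) - igraph::vcount(g)))
  out[lin] <- igraph::components(g)$membership
  out
}

# recompute true contact classes on the final geometry (divisions change
# which cells touch the central L2 cell)
refresh_truth_contacts <- function(volume, truth) {
  g <- build_adjacency(volume, min_contact_area = 0, keep_faces = FALSE)
  cls <- assign_contact_degrees(g, truth$meta$central_label)
  truth$cells$contact_class <- unname(cls[as.character(truth$cells$cell_label)])
  truth$cells$contact_class[
    truth$cells$cell_label == truth$meta$central_label] <- "central_L2"
  if (!is.na(truth$meta$central_l3_label))
    truth$cells$contact_class[
      truth$cells$cell_label == truth$meta$central_l3_label] <- "central_L3"
  truth
}

# extent fraction f whose periclinal split puts `volume_fraction` of the
# cell's voxels on the basal (deeper) side
split_fraction_for_volume <- function(volume, cell_label, volume_fraction) {
  idx <- label_indices(volume, cell_label)
  dist2 <- exterior_distance(volume)
  s <- -sqrt(dist2[idx])
  thr <- quantile(s, volume_fraction, names = FALSE)
  fr <- (thr - min(s)) / (max(s) - min(s))
  min(max(fr, 0.1), 0.9)
}
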