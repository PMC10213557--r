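#' Merge a daughter pair into the mother-cell mask
#'
#' @param volume a [labeled_volume()].
#' @param label_a,label_b adjacent daughter labels.
#' @return logical 3D array (full grid) of the 6-connected union.
#' @export
merge_pair <- function(volume, label_a, label_b) {
  mask <- volume$labels == label_a | volume$labels == label_b
  if (!any(volume$labels == label_a) || !any(volume$labels == label_b))
    stop("label absent from volume")
  if (!mask_connected(mask))
    stop("union of ", label_a, " and ", label_b,
         " is not 6-connected; not a daughter pair")
  mask
}

# 6-connectivity check on the cropped mask via BFS over voxel adjacency
mask_connected <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(FALSE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(sub)
  lin <- which(sub)
  id <- array(0L, d)
  id[lin] <- seq_along(lin)
  edges <- list()
  arr <- which(sub, arr.ind = TRUE)
  for (ax in 1:3) {
    nb <- arr
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    ok[ok] <- sub[nb[ok, , drop = FALSE]]
    if (any(ok))
      edges[[ax]] <- cbind(id[arr[ok, , drop = FALSE]],
                           id[nb[ok, , drop = FALSE]])
  }
  em <- do.call(rbind, edges)
  if (is.null(em)) return(length(lin) == 1L)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(lin) - igraph::vcount(g)))
  igraph::components(g)$no == 1L
}

# quasi-uniform directions on the half-sphere (z >= 0), Fibonacci lattice
fibonacci_half_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                      # upper half only
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# directions within an angular cap around a unit vector u
cap_directions <- function(u, n, cap_deg) {
  b <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- b - sum(b * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  i <- seq_len(n) - 0.5
  ct <- 1 - (i / n) * (1 - cos(cap_deg * pi / 180))
  st <- sqrt(pmax(1 - ct^2, 0))
  phi <- pi * (1 + sqrt(5)) * i
  dir <- outer(ct, u) + outer(st * cos(phi), e1) + outer(st * sin(phi), e2)
  dir / sqrt(rowSums(dir^2))
}

# Cross-section areas of a voxel point cloud for a set of directions: a
# voxel-scale slab through the centroid with a triangular weighting window
# (width 2h), which antialiases the voxel-center quantization that plain
# box counting suffers on oblique directions. Normalized so that an
# axis-aligned solid yields its exact section area.
slab_areas <- function(coords, centroid, dirs, voxel_vol, h) {
  cc <- sweep(coords, 2, centroid)
  areas <- numeric(nrow(dirs))
  chunk <- 100L
  for (s in seq(1L, nrow(dirs), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(dirs))
    proj <- cc %*% t(dirs[s:e, , drop = FALSE])
    w <- matrix(pmax(0, 1 - abs(proj) / h), nrow = nrow(proj))
    areas[s:e] <- colSums(w) * voxel_vol / h
  }
  areas
}

#' Predict the geometric division plane (shortest-wall rule)
#'
#' Finds the plane through the mask centroid with minimal cross-section
#' area — the geometric rule for symmetric divisions (new wall = shortest
#' wall through the cell center). The search scans a quasi-uniform Fibonacci
#' grid of directions on the half-sphere and then refines locally with
#' shrinking angular caps. Cross-section area is measured by one-voxel-thick
#' slab counting with oblique-thickness correction.
#'
#' @param mask logical 3D array of the mother cell (>= 125 voxels).
#' @param voxel_size `(dz, dy, dx)` um.
#' @param n_directions size of the global direction grid.
#' @param refine_iters local refinement rounds (cap 8 then 3 degrees).
#' @return list `normal` (unit `(x, y, z)`), `area_um2` (minimal section).
#' @export
predict_division_plane <- function(mask, voxel_size, n_directions = 500L,
                                   refine_iters = 2L) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 125L) stop("mother mask smaller than 125 voxels")
  coords <- voxel_centers(idx, voxel_size)
  ctr <- colMeans(coords)
  vv <- prod(voxel_size)
  h <- 2 * mean(voxel_size)
  dirs <- fibonacci_half_sphere(n_directions)
  areas <- slab_areas(coords, ctr, dirs, vv, h)
  best <- which.min(areas)
  u <- dirs[best, ]
  a <- areas[best]
  caps <- c(8, 3, 1.5)
  for (it in seq_len(refine_iters)) {
    cd <- cap_directions(u, 80L, caps[min(it, length(caps))])
    ca <- slab_areas(coords, ctr, cd, vv, h)
    if (min(ca) < a) {
      a <- min(ca)
      u <- cd[which.min(ca), ]
    }
  }
  list(normal = u, area_um2 = a, centroid = ctr)
}

#' Observed-predicted (o-p) angle between two plane normals
#'
#' `acos(|n1 . n2|)` in degrees, folded to `[0, 90]`; symmetric in its
#' arguments and invariant to sign flips of either normal.
#'
#' @param n1,n2 non-zero 3-vectors.
#' @return angle in degrees.
#' @export
op_angle <- function(n1, n2) {
  l1 <- sqrt(sum(n1^2)); l2 <- sqrt(sum(n2^2))
  if (l1 < 1e-12 || l2 < 1e-12) stop("zero-length normal")
  acos(pmin(abs(sum(n1 * n2)) / (l1 * l2), 1)) * 180 / pi
}

#' Classify a division orientation
#'
#' The angle between the new wall's normal and the local radial
#' (surface-normal) direction decides the class: within
#' `periclinal_max_deg` (default 30) of radial is periclinal (wall parallel
#' to the surface), beyond `anticlinal_min_deg` (default 60) anticlinal,
#' oblique in between.
#'
#' @param wall_normal unit normal of the observed daughter interface.
#' @param radial_dir unit local radial (outward) direction.
#' @param periclinal_max_deg,anticlinal_min_deg class boundaries in degrees.
#' @return `"periclinal"`, `"anticlinal"` or `"oblique"`.
#' @export
classify_orientation <- function(wall_normal, radial_dir,
                                 periclinal_max_deg = 30,
                                 anticlinal_min_deg = 60) {
  th <- op_angle(wall_normal, radial_dir)
  if (th < periclinal_max_deg) "periclinal"
  else if (th > anticlinal_min_deg) "anticlinal"
  else "oblique"
}

# observed wall normal of a pair from the shared boundary faces (PCA plane)
observed_wall_normal <- function(graph, a, b) {
  f <- graph$faces
  sel <- (f$a == min(a, b) & f$b == max(a, b))
  pts <- as.matrix(f[sel, c("x", "y", "z"), drop = FALSE])
  if (nrow(pts) < 3L) stop("pair ", a, "-", b, " has too small an interface")
  ev <- eigen(stats::cov(sweep(pts, 2, colMeans(pts))), symmetric = TRUE)
  n <- ev$vectors[, which.min(ev$values)]
  n / sqrt(sum(n^2))
}

#' Detect recent divisions by geometric wall continuity
#'
#' Scans every adjacent division-compatible cell pair (both cells in the
#' same layer, or an L2-L3 pair) and measures the junction wall angle; a
#' pair at or above the continuity threshold is flagged a recent division.
#' Recent pairs carry the full division call: the shortest-wall plane
#' prediction on the merged mother, the observed-predicted angle, the
#' orientation class against the local radial direction, and the daughter
#' volume ratio. Pairs whose junction angle is undefined (no qualifying side
#' context) are skipped with a message.
#'
#' @param volume a [labeled_volume()].
#' @param annotation an [annotate_ovule()] result.
#' @param config a [default_config()].
#' @param graph adjacency graph (defaults to the annotation's).
#' @param pairs optional two-column matrix of label pairs to restrict to.
#' @return tibble of division calls, one row per evaluated pair: labels,
#'   layers, `continuity_angle_deg`, `is_recent`, and for recent pairs the
#'   predicted/observed normals, `op_angle_deg`, `orientation`,
#'   `volume_ratio`.
#' @export
detect_recent_divisions <- function(volume, annotation,
                                    config = default_config(),
                                    graph = annotation$graph,
                                    pairs = NULL) {
  layers <- annotation$layers
  if (is.null(pairs)) {
    e <- graph$edges[graph$edges$a != 0L, , drop = FALSE]
    la <- layers[as.character(e$a)]
    lb <- layers[as.character(e$b)]
    ok <- (la == lb & la %in% c("L1", "L2", "L3")) |
      (la == "L2" & lb == "L3") | (la == "L3" & lb == "L2")
    pairs <- cbind(e$a[ok], e$b[ok])
  }
  if (nrow(pairs) == 0L) return(division_call_prototype())
  dist2 <- exterior_distance(volume)
  rows <- vector("list", nrow(pairs))
  for (q in seq_len(nrow(pairs))) {
    a <- pairs[q, 1]; b <- pairs[q, 2]
    # upper = the cell nearer the surface (smaller distance-to-exterior)
    ca <- colMeans(cell_coords(volume, a))
    cb <- colMeans(cell_coords(volume, b))
    da <- interp_field(dist2, volume$voxel_size, ca)
    db <- interp_field(dist2, volume$voxel_size, cb)
    if (da > db) { tmp <- a; a <- b; b <- tmp; tmp <- ca; ca <- cb; cb <- tmp }
    ja <- tryCatch(
      junction_wall_angle(volume, graph, a, b, config$min_side_area_um2),
      error = function(e) NULL)
    if (is.null(ja)) {
      message("pair ", a, "-", b, ": junction angle undefined; skipped")
      next
    }
    ang <- ja$mean_angle_deg
    recent <- ang >= config$continuity_threshold_deg
    va <- measure_volume(volume, a); vb <- measure_volume(volume, b)
    row <- tibble::tibble(
      label_upper = a, label_lower = b,
      layer_upper = unname(layers[as.character(a)]),
      layer_lower = unname(layers[as.character(b)]),
      continuity_angle_deg = ang, is_recent = recent,
      volume_ratio = max(va, vb) / min(va, vb),
      op_angle_deg = NA_real_, orientation = NA_character_,
      pred_nx = NA_real_, pred_ny = NA_real_, pred_nz = NA_real_,
      obs_nx = NA_real_, obs_ny = NA_real_, obs_nz = NA_real_)
    if (recent) {
      full <- tryCatch({
        mother <- merge_pair(volume, a, b)
        pred <- predict_division_plane(mother, volume$voxel_size,
                                       config$n_plane_directions,
                                       config$plane_refine_iters)
        obs <- observed_wall_normal(graph, a, b)
        rad <- radial_direction(dist2, volume$voxel_size, pred$centroid)
        list(pred = pred, obs = obs, rad = rad)
      }, error = function(e) {
        message("pair ", a, "-", b, ": plane prediction failed (",
                conditionMessage(e), ")")
        NULL
      })
      if (!is.null(full)) {
        row$op_angle_deg <- op_angle(full$pred$normal, full$obs)
        row$orientation <- classify_orientation(full$obs, full$rad,
                                                config$periclinal_max_deg,
                                                config$anticlinal_min_deg)
        row[, c("pred_nx", "pred_ny", "pred_nz")] <- as.list(full$pred$normal)
        row[, c("obs_nx", "obs_ny", "obs_nz")] <- as.list(full$obs)
      }
    }
    rows[[q]] <- row
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) division_call_prototype() else out
}

division_call_prototype <- function() {
  tibble::tibble(label_upper = integer(), label_lower = integer(),
                 layer_upper = character(), layer_lower = character(),
                 continuity_angle_deg = double(), is_recent = logical(),
                 volume_ratio = double(), op_angle_deg = double(),
                 orientation = character(),
                 pred_nx = double(), pred_ny = double(), pred_nz = double(),
                 obs_nx = double(), obs_ny = double(), obs_nz = double())
}

# trilinear-free nearest-voxel lookup of a field at physical point p
interp_field <- function(field, voxel_size, p) {
  d <- dim(field)
  i <- min(max(ceiling(p[1] / voxel_size[3]), 1L), d[3])
  j <- min(max(ceiling(p[2] / voxel_size[2]), 1L), d[2])
  k <- min(max(ceiling(p[3] / voxel_size[1]), 1L), d[1])
  field[k, j, i]
}

#' Classify an ovule as Type 1 or Type 2
#'
#' Type 2 ovules show geometric wall continuity between the central L2 and
#' central L3 cells (junction angle at or above the continuity threshold),
#' the signature of a recent periclinal division of the archesporial cell;
#' Type 1 ovules do not. An ovule with no central L3 cell is Type 1, flagged.
#'
#' @param volume a [labeled_volume()].
#' @param annotation an [annotate_ovule()] result.
#' @param config a [default_config()].
#' @return tibble: `type` (`"Type1"`/`"Type2"`), `continuity_angle_deg`,
#'   `threshold_deg`, `missing_central_l3`.
#' @export
classify_ovule_type <- function(volume, annotation,
                                config = default_config()) {
  thr <- config$continuity_threshold_deg
  if (is.na(annotation$central_l3))
    return(tibble::tibble(type = "Type1", continuity_angle_deg = NA_real_,
                          threshold_deg = thr, missing_central_l3 = TRUE))
  ja <- tryCatch(
    junction_wall_angle(volume, annotation$graph, annotation$central_l2,
                        annotation$central_l3, config$min_side_area_um2),
    error = function(e) NULL)
  if (is.null(ja))
    return(tibble::tibble(type = "Type1", continuity_angle_deg = NA_real_,
                          threshold_deg = thr, missing_central_l3 = TRUE))
  tibble::tibble(
    type = if (ja$mean_angle_deg >= thr) "Type2" else "Type1",
    continuity_angle_deg = ja$mean_angle_deg,
    threshold_deg = thr, missing_central_l3 = FALSE)
}

#' Cluster daughter volume ratios (optimal 1D k-means)
#'
#' Globally optimal, deterministic 1D k-means by dynamic programming,
#' clusters ordered by ascending mean. Used to ask whether central-pair
#' volume ratios split into a symmetric (ratio near 1) and an asymmetric
#' (ratio above 2) class.
#'
#' @param ratios numeric vector of volume ratios (each >= 1).
#' @param k number of clusters (default 2).
#' @return list `assignments` (1-based cluster per input, ascending means),
#'   `means`, `wss`.
#' @export
cluster_volume_ratios <- function(ratios, k = 2L) {
  if (length(ratios) < k) stop("need at least k = ", k, " values")
  km <- kmeans_1d_dp(ratios, k)
  list(assignments = km$cluster, means = km$centers, wss = km$tot_withinss)
}
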