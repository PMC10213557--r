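#' Two-cell interface (wall) mesh
#'
#' The shared wall between two adjacent cells, extracted as the subset of the
#' smaller label's iso-surface whose triangles face the other label: each
#' triangle is attributed to the region found just across it (sampling the
#' label grid a fraction of a voxel on either side of the triangle centroid).
#' Computing the patch from the canonical (smaller) label of the pair makes
#' `interface_mesh(A, B)` and `interface_mesh(B, A)` identical, so the area
#' is exactly symmetric. A least-squares plane (principal-axis fit of the
#' patch vertices) and its RMS residual quantify wall planarity.
#'
#' @param volume a [labeled_volume()].
#' @param label_a,label_b adjacent cell labels (0 / `"EXTERIOR"` allowed for
#'   `label_b`).
#' @param smoothing_iters Taubin iterations for the underlying cell surface.
#' @return an `interface_mesh` list: `mesh`, `area_um2`, `plane_point`,
#'   `plane_normal` (unit), `rms_residual_um`, `pair`.
#' @export
interface_mesh <- function(volume, label_a, label_b, smoothing_iters = 5L) {
  if (identical(label_b, "EXTERIOR")) label_b <- 0L
  label_a <- as.integer(label_a); label_b <- as.integer(label_b)
  if (label_a == label_b) stop("need two distinct labels")
  # canonical source cell: the smaller nonzero label
  src <- min(label_a, label_b); oth <- max(label_a, label_b)
  if (src == 0L) { src <- oth; oth <- 0L }
  cm <- extract_cell_mesh(volume, src, smoothing_iters = smoothing_iters)
  mesh <- cm$mesh
  nb <- triangle_neighbors(volume, mesh, src)
  keep <- nb == oth
  if (!any(keep))
    stop("labels ", label_a, " and ", label_b, " are not adjacent")
  tri <- mesh$triangles[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tri)))
  remap <- match(tri, used)
  patch <- surface_mesh(mesh$vertices[used, , drop = FALSE],
                        matrix(remap, ncol = 3))
  v <- patch$vertices
  ctr <- colMeans(v)
  ev <- eigen(stats::cov(sweep(v, 2, ctr)), symmetric = TRUE)
  normal <- ev$vectors[, which.min(ev$values)]
  normal <- normal / sqrt(sum(normal^2))
  res <- sqrt(mean((sweep(v, 2, ctr) %*% normal)^2))
  structure(list(mesh = patch, area_um2 = mesh_area(patch),
                 plane_point = ctr, plane_normal = normal,
                 rms_residual_um = res,
                 pair = c(min(label_a, label_b), max(label_a, label_b))),
            class = "interface_mesh")
}

#' @exportS3Method base::print
print.interface_mesh <- function(x, ...) {
  cat(sprintf(
    "<interface_mesh> cells %d-%d: area %.4g um^2, planarity RMS %.3g um\n",
    x$pair[1], x$pair[2], x$area_um2, x$rms_residual_um))
  invisible(x)
}

# Label of the region just across each triangle of a cell's surface mesh.
# Samples the grid at centroid +/- eps along the triangle normal; the side
# that is not `label` is the neighbor (0 = background/exterior).
triangle_neighbors <- function(volume, mesh, label, eps_vox = 0.75) {
  v <- mesh$vertices
  tri <- mesh$triangles
  c1 <- v[tri[, 1], , drop = FALSE]
  c2 <- v[tri[, 2], , drop = FALSE]
  c3 <- v[tri[, 3], , drop = FALSE]
  cen <- (c1 + c2 + c3) / 3
  e1 <- c2 - c1; e2 <- c3 - c1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  nn[nn < 1e-12] <- 1
  eps <- eps_vox * mean(volume$voxel_size)
  lab_at <- function(p) {
    d <- dim(volume$labels)
    i <- pmin(pmax(ceiling(p[, 1] / volume$voxel_size[3]), 1L), d[3])
    j <- pmin(pmax(ceiling(p[, 2] / volume$voxel_size[2]), 1L), d[2])
    k <- pmin(pmax(ceiling(p[, 3] / volume$voxel_size[1]), 1L), d[1])
    volume$labels[cbind(k, j, i)]
  }
  shift <- cbind(nx, ny, nz) / nn * eps
  la <- lab_at(cen + shift)
  lb <- lab_at(cen - shift)
  out <- ifelse(la != label, la, lb)
  # if both sides read back as `label` (very oblique triangle), look farther
  amb <- out == label
  if (any(amb)) {
    la2 <- lab_at(cen[amb, , drop = FALSE] + 2 * shift[amb, , drop = FALSE])
    lb2 <- lab_at(cen[amb, , drop = FALSE] - 2 * shift[amb, , drop = FALSE])
    out[amb] <- ifelse(la2 != label, la2, lb2)
  }
  out
}

#' Apical and basal wall areas of the central L2 cell
#'
#' The apical wall is the summed interface area between the central L2 cell
#' and all of its L1 neighbors; the basal wall is its interface with the
#' central L3 (stack) cell. Their ratio tracks the trapezoidal shape of the
#' presumptive megaspore mother cell.
#'
#' @param volume a [labeled_volume()].
#' @param annotation an [annotate_ovule()] result.
#' @param graph adjacency graph (defaults to the one in `annotation`).
#' @return list `apical_um2`, `basal_um2`, `ratio`; basal and ratio are `NA`
#'   when no central L3 cell is present.
#' @export
apical_basal_walls <- function(volume, annotation, graph = annotation$graph) {
  central <- annotation$central_l2
  nb <- cell_neighbors(graph, central)
  l1 <- nb[annotation$layers[as.character(nb)] == "L1"]
  if (length(l1) == 0L) stop("central L2 cell has no L1 neighbor")
  apical <- sum(vapply(l1, function(l)
    interface_mesh(volume, central, l)$area_um2, numeric(1)))
  if (is.na(annotation$central_l3)) {
    list(apical_um2 = apical, basal_um2 = NA_real_, ratio = NA_real_)
  } else {
    basal <- interface_mesh(volume, central, annotation$central_l3)$area_um2
    list(apical_um2 = apical, basal_um2 = basal, ratio = apical / basal)
  }
}

#' Junction wall angle between two adjacent cells
#'
#' Quantifies the geometric continuity of the walls of a putative daughter
#' pair. For every third region X (a neighbor cell or the exterior) adjacent
#' to both cells with side patches of at least `min_side_area`, three points
#' are placed automatically: the centroids of the upper-X and lower-X wall
#' patches and the junction point J where the two patches meet; the angle at
#' J between the rays toward the two patch centroids is reported per side,
#' together with the mean over sides. Perfect wall continuity gives angles
#' near 180 degrees.
#'
#' @param volume a [labeled_volume()].
#' @param graph adjacency graph built with `keep_faces = TRUE`.
#' @param upper_label,lower_label the candidate daughter pair.
#' @param min_side_area minimum side patch area, um^2.
#' @return list: `records` (tibble: side label, angle_deg, junction and
#'   centroid coordinates) and `mean_angle_deg`.
#' @export
junction_wall_angle <- function(volume, graph, upper_label, lower_label,
                                min_side_area = 4.0) {
  f <- graph$faces
  if (is.null(f)) stop("adjacency graph built with keep_faces = FALSE")
  up <- as.integer(upper_label); lo <- as.integer(lower_label)
  fu <- f[f$a == up | f$b == up, , drop = FALSE]
  fl <- f[f$a == lo | f$b == lo, , drop = FALSE]
  other <- function(sub, lbl) ifelse(sub$a == lbl, sub$b, sub$a)
  ou <- other(fu, up); ol <- other(fl, lo)
  sides <- intersect(setdiff(unique(ou), lo), setdiff(unique(ol), up))
  vox <- mean(volume$voxel_size)
  d_loc <- 8 * vox       # wall centroids are taken near the junction
  recs <- list()
  for (X in sides) {
    pu <- fu[ou == X, c("x", "y", "z"), drop = FALSE]
    pl <- fl[ol == X, c("x", "y", "z"), drop = FALSE]
    area_u <- sum(face_area_of(fu[ou == X, ], volume$voxel_size))
    area_l <- sum(face_area_of(fl[ol == X, ], volume$voxel_size))
    if (area_u < min_side_area || area_l < min_side_area) next
    mu <- as.matrix(pu); ml <- as.matrix(pl)
    # triple junction: face centers of either patch close to the other
    # patch (both patches tile the continuous boundary of X, so they meet
    # along the junction curve whatever the wall displacement)
    dd <- outer(rowSums(mu^2), rowSums(ml^2), "+") - 2 * mu %*% t(ml)
    near <- sqrt(pmax(dd, 0)) < 1.8 * vox
    if (!any(near)) next
    jpts <- rbind(mu[rowSums(near) > 0, , drop = FALSE],
                  ml[colSums(near) > 0, , drop = FALSE])
    # Compact patches — the usual geometry of a cell side in tissue — are
    # measured as one record per junction component with the full wall
    # patches. Large wrap-around patches (typically the exterior of an
    # isolated fixture, which can encircle the pair) are decomposed into
    # planar sub-walls (same face orientation, connected) and every
    # parallel upper/lower sub-wall pair near enough to continue one
    # another is measured separately, so distant wall regions cannot
    # dilute or cancel a local discontinuity.
    diam <- function(p) max(apply(p, 2, function(v) diff(range(v))))
    wrap <- max(diam(mu), diam(ml)) > 2 * d_loc
    if (!wrap) {
      J <- colMeans(jpts)
      tdir <- NULL
      if (nrow(jpts) >= 3L) {
        ev <- eigen(stats::cov(sweep(jpts, 2, J)), symmetric = TRUE)
        if (ev$values[1] > 4 * max(ev$values[2], 1e-12))
          tdir <- ev$vectors[, 1]
      }
      rec <- angle_record(X, J, mu, ml, tdir, vox)
      if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
    } else {
      axis_u <- fu$axis[ou == X]
      axis_l <- fl$axis[ol == X]
      subs_u <- planar_subpatches(mu, axis_u, vox)
      subs_l <- planar_subpatches(ml, axis_l, vox)
      fa_u <- face_area_of(fu[ou == X, ][1, ], volume$voxel_size)
      fa_l <- face_area_of(fl[ol == X, ][1, ], volume$voxel_size)
      for (su in subs_u) for (sl in subs_l) {
        if (su$axis != sl$axis) next      # only parallel walls continue
        if (nrow(su$pts) * fa_u < min_side_area ||
            nrow(sl$pts) * fa_l < min_side_area) next
        dd2 <- outer(rowSums(su$pts^2), rowSums(sl$pts^2), "+") -
          2 * su$pts %*% t(sl$pts)
        dmin <- sqrt(max(min(dd2), 0))
        if (dmin > d_loc) next
        hit <- which(sqrt(pmax(dd2, 0)) <= dmin + 0.75 * vox,
                     arr.ind = TRUE)
        mids <- (su$pts[hit[, 1], , drop = FALSE] +
                   sl$pts[hit[, 2], , drop = FALSE]) / 2
        tdir <- NULL
        if (nrow(mids) >= 3L) {
          ev <- eigen(stats::cov(sweep(mids, 2, colMeans(mids))),
                      symmetric = TRUE)
          if (ev$values[1] > 4 * max(ev$values[2], 1e-12))
            tdir <- ev$vectors[, 1]
        }
        # the junction point sits where each wall ends (its edge facing
        # the other wall) — a point midway between offset walls would be
        # collinear with the two wall centroids by construction. Measure
        # at both wall edges and average.
        j_up <- colMeans(su$pts[unique(hit[, 1]), , drop = FALSE])
        j_lo <- colMeans(sl$pts[unique(hit[, 2]), , drop = FALSE])
        r1 <- angle_record(X, j_up, su$pts, sl$pts, tdir, vox)
        r2 <- angle_record(X, j_lo, su$pts, sl$pts, tdir, vox)
        if (!is.null(r1) && !is.null(r2)) {
          rec <- r1
          rec$angle_deg <- (r1$angle_deg + r2$angle_deg) / 2
          rec[, c("jx", "jy", "jz")] <-
            as.list((j_up + j_lo) / 2)
          recs[[length(recs) + 1L]] <- rec
        }
      }
    }
  }
  if (length(recs) == 0L)
    stop("no qualifying side context; junction angle undefined for pair ",
         up, "-", lo)
  records <- dplyr::bind_rows(recs)
  list(records = records, mean_angle_deg = mean(records$angle_deg))
}

# one junction-angle record: angle at J between rays to the two wall
# centroids, measured in the plane perpendicular to the junction direction
# when one is identifiable
angle_record <- function(X, J, mu_loc, ml_loc, tdir, vox) {
  if (nrow(mu_loc) < 3L || nrow(ml_loc) < 3L) return(NULL)
  p_up <- colMeans(mu_loc)
  p_lo <- colMeans(ml_loc)
  v1 <- p_up - J
  v2 <- p_lo - J
  if (!is.null(tdir)) {
    v1 <- v1 - sum(v1 * tdir) * tdir
    v2 <- v2 - sum(v2 * tdir) * tdir
  }
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < vox / 4 || n2 < vox / 4) return(NULL)
  ang <- acos(pmin(pmax(sum(v1 * v2) / (n1 * n2), -1), 1)) * 180 / pi
  tibble::tibble(side = X, angle_deg = ang,
                 jx = J[1], jy = J[2], jz = J[3],
                 upx = p_up[1], upy = p_up[2], upz = p_up[3],
                 lox = p_lo[1], loy = p_lo[2], loz = p_lo[3])
}

# decompose a voxel-face patch into planar sub-walls: faces of the same
# orientation, connected at the voxel scale
planar_subpatches <- function(pts, axis, vox) {
  out <- list()
  for (ax in sort(unique(axis))) {
    sel <- axis == ax
    for (comp in split_components(pts[sel, , drop = FALSE], 1.6 * vox))
      out[[length(out) + 1L]] <- list(axis = ax, pts = comp)
  }
  out
}

# single-linkage connected components of a small point set
split_components <- function(pts, thr) {
  n <- nrow(pts)
  if (n == 0L) return(list())
  if (n == 1L) return(list(pts))
  dd <- as.matrix(dist(pts)) <= thr
  g <- igraph::graph_from_adjacency_matrix(dd, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  lapply(split(seq_len(n), comp), function(i) pts[i, , drop = FALSE])
}

face_area_of <- function(faces, voxel_size) {
  fa <- c(voxel_size[2] * voxel_size[3], voxel_size[1] * voxel_size[3],
          voxel_size[1] * voxel_size[2])
  fa[faces$axis]
}
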