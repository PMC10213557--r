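test_that("merging a daughter pair conserves volume and centroid", {
  vol <- stacked_boxes(side = 10L)
  mother <- merge_pair(vol, 1L, 2L)
  expect_equal(sum(mother), 2 * 1000)
  ca <- colMeans(cell_coords(vol, 1L))
  cb <- colMeans(cell_coords(vol, 2L))
  idx <- which(mother, arr.ind = TRUE)
  cm <- colMeans(primordium3d:::voxel_centers(idx, vol$voxel_size))
  expect_lt(max(abs(cm - (ca + cb) / 2)), 1e-9)
  # non-adjacent labels refuse to merge
  lab <- array(0L, c(8, 8, 8))
  lab[2:3, 2:3, 2:3] <- 1L
  lab[6:7, 6:7, 6:7] <- 2L
  far <- labeled_volume(lab, c(1, 1, 1))
  expect_error(merge_pair(far, 1L, 2L), "connected")
})

test_that("shortest-wall prediction matches brute force on convex bodies", {
  # box 10 x 20 x 40 um: minimal section 10 x 20 through the center
  lab <- array(FALSE, c(44, 24, 14))
  lab[3:42, 3:22, 3:12] <- TRUE
  pp <- predict_division_plane(lab, c(1, 1, 1))
  expect_lt(op_angle(pp$normal, c(0, 0, 1)), 5)
  expect_lt(abs(pp$area_um2 - 200) / 200, 0.10)
  # a 10x denser global direction grid cannot do meaningfully better
  dense <- primordium3d:::fibonacci_half_sphere(5000)
  idx <- which(lab, arr.ind = TRUE)
  coords <- primordium3d:::voxel_centers(idx, c(1, 1, 1))
  areas <- primordium3d:::slab_areas(coords, colMeans(coords), dense, 1, 2)
  expect_lte(pp$area_um2, min(areas) * 1.02)

  # prolate ellipsoid: minimal section is perpendicular to the long axis
  m <- ellipsoid_mask(10, 10, 30)
  pe <- predict_division_plane(m, c(1, 1, 1))
  expect_lt(op_angle(pe$normal, c(0, 0, 1)), 5)
  expect_lt(abs(pe$area_um2 - pi * 100) / (pi * 100), 0.10)

  # a ball is degenerate: any direction, area ~ pi r^2, no error
  pb <- predict_division_plane(ball_mask(12), c(1, 1, 1))
  expect_lt(abs(pb$area_um2 - pi * 144) / (pi * 144), 0.10)
})

test_that("o-p angle folds to [0, 90] and is symmetric", {
  expect_equal(op_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(op_angle(c(0, 0, 1), c(0, 0, -1)), 0)
  expect_equal(op_angle(c(1, 0, 0), c(0, 0, 1)), 90)
  a <- c(0.3, -0.5, 0.81); b <- c(-0.2, 0.9, 0.38)
  expect_equal(op_angle(a, b), op_angle(b, a))
  expect_equal(op_angle(a, b), op_angle(-a, b))
  expect_error(op_angle(c(0, 0, 0), b), "zero")
})

test_that("planted mid-plane splits of a convex cell are re-predicted", {
  # split an ellipsoid through its center, perpendicular to the long axis;
  # the shortest-wall rule must recover that plane
  m <- ellipsoid_mask(9, 11, 22)
  lab <- array(0L, dim(m))
  idx <- which(m, arr.ind = TRUE)
  mid <- (dim(m)[1] + 1) / 2
  lab[m] <- ifelse(idx[, 1] <= mid, 1L, 2L)
  vol <- labeled_volume(lab, c(1, 1, 1))
  g <- build_adjacency(vol)
  mother <- merge_pair(vol, 1L, 2L)
  pp <- predict_division_plane(mother, c(1, 1, 1))
  obs <- primordium3d:::observed_wall_normal(g, 1L, 2L)
  expect_lte(op_angle(pp$normal, obs), 5)
})

test_that("orientation classes follow the wall-normal vs radial angle", {
  expect_equal(classify_orientation(c(0, 0, 1), c(0, 0, 1)), "periclinal")
  expect_equal(classify_orientation(c(1, 0, 0), c(0, 0, 1)), "anticlinal")
  mid <- c(sin(45 * pi / 180), 0, cos(45 * pi / 180))
  expect_equal(classify_orientation(mid, c(0, 0, 1)), "oblique")
})

test_that("division detection separates recent divisions from the rest", {
  gen <- test_dome(rng_seed = 7, target = 1500)
  pd <- plant_division(gen$volume, gen$truth, gen$truth$meta$central_label,
                       "periclinal", f = 0.5, jitter = 0, rng_seed = 2)
  ann <- annotate_ovule(pd$volume)
  calls <- detect_recent_divisions(pd$volume, ann)
  planted <- calls$label_upper == pd$labels["apical"] &
    calls$label_lower == pd$labels["basal"]
  expect_true(any(planted))
  expect_true(all(calls$is_recent[planted]))
  expect_equal(calls$orientation[planted], "periclinal")
  # false positives among the never-divided pairs stay rare
  expect_lte(mean(calls$is_recent[!planted]), 0.1)
})

test_that("ovule types reflect central-pair wall continuity", {
  gen2 <- test_dome(rng_seed = 7, target = 1200)
  pd <- plant_division(gen2$volume, gen2$truth,
                       gen2$truth$meta$central_label, "periclinal",
                       f = 0.5, jitter = 0, rng_seed = 2)
  ann2 <- annotate_ovule(pd$volume)
  expect_equal(classify_ovule_type(pd$volume, ann2)$type, "Type2")
  gen1 <- test_dome(rng_seed = 7, target = 1200, stack_seed = TRUE)
  ann1 <- annotate_ovule(gen1$volume)
  ty1 <- classify_ovule_type(gen1$volume, ann1)
  expect_equal(ty1$type, "Type1")
  expect_lt(ty1$continuity_angle_deg, 160)
  # missing central L3 is flagged Type1
  vol <- slab_stack()
  g <- build_adjacency(vol)
  ann <- list(central_l2 = 2L, central_l3 = NA_integer_, graph = g)
  ty <- classify_ovule_type(vol, ann)
  expect_equal(ty$type, "Type1")
  expect_true(ty$missing_central_l3)
})

test_that("volume-ratio clustering is globally optimal and ordered", {
  x <- c(1.0, 1.1, 0.95, 1.05, 0.9, 1.0, 2.2, 2.4, 2.3, 2.5)
  cl <- cluster_volume_ratios(x, 2)
  expect_lt(abs(cl$means[1] - 1.0) / 1.0, 0.10)
  expect_lt(abs(cl$means[2] - 2.35) / 2.35, 0.10)
  expect_equal(as.integer(table(cl$assignments)), c(6L, 4L))
  # brute force over contiguous partitions of the sorted values
  xs <- sort(x)
  best <- Inf
  for (cut in 1:(length(xs) - 1)) {
    w <- sum((xs[1:cut] - mean(xs[1:cut]))^2) +
      sum((xs[(cut + 1):length(xs)] - mean(xs[(cut + 1):length(xs)]))^2)
    best <- min(best, w)
  }
  expect_equal(cl$wss, best, tolerance = 1e-12)

  same <- cluster_volume_ratios(rep(1.5, 5), 2)
  expect_equal(same$wss, 0)
  expect_error(cluster_volume_ratios(c(1, 2), 3), "at least")
})
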