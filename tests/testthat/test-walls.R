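test_that("interface meshes recover planar walls between stacked cubes", {
  vol <- stacked_boxes(side = 20L)
  im <- interface_mesh(vol, 1L, 2L)
  expect_lt(abs(im$area_um2 - 400) / 400, 0.10)
  expect_lt(op_angle(im$plane_normal, c(0, 0, 1)), 3)
  expect_lt(im$rms_residual_um, 0.5)
  im_rev <- interface_mesh(vol, 2L, 1L)
  expect_identical(im$area_um2, im_rev$area_um2)   # exactly symmetric
  expect_error(interface_mesh(vol, 1L, 99L))
})

test_that("curved interfaces report a larger planarity residual", {
  # hemispherical cap carved out of a box: label 2 below a spherical
  # boundary, label 1 above
  n <- 34L
  ax <- seq_len(n) - (n + 1) / 2
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  lab <- array(1L, c(n, n, n))
  lab[r2 <= 14^2 & slice.index(lab, 1) <= n / 2] <- 2L
  vol <- labeled_volume(lab, c(1, 1, 1))
  curved <- interface_mesh(vol, 1L, 2L)
  flat <- interface_mesh(stacked_boxes(side = 20L), 1L, 2L)
  expect_gt(curved$rms_residual_um, 4 * flat$rms_residual_um)
})

test_that("apical wall area sums over all L1 contacts", {
  # central cell (label 4) with three epidermal plates of distinct contact
  # areas 100, 50, 30 um^2 on top and a basal cell below
  lab <- array(0L, c(12, 16, 16))
  lab[2:5, 2:15, 2:15] <- 5L                    # basal cell
  lab[6:9, 2:15, 2:15] <- 4L                    # central cell, top 14 x 14
  lab[10:11, 2:11, 2:11] <- 1L                  # 10 x 10 = 100 um^2
  lab[10:11, 2:11, 12:15] <- 2L                 # 10 x 4  =  40 um^2
  lab[10:11, 12:15, 2:15] <- 3L                 #  4 x 14 =  56 um^2
  vol <- labeled_volume(lab, c(1, 1, 1))
  g <- build_adjacency(vol)
  a1 <- contact_area(g, 4, 1)
  a2 <- contact_area(g, 4, 2)
  a3 <- contact_area(g, 4, 3)
  expect_equal(a1 + a2 + a3, 14 * 14)
  ann <- list(central_l2 = 4L, central_l3 = 5L,
              layers = stats::setNames(
                c("L1", "L1", "L1", "L2", "L3"),
                c("1", "2", "3", "4", "5")),
              graph = g)
  walls <- apical_basal_walls(vol, ann)
  # mesh areas of small flat patches lose an edge-bevel band (~1 voxel of
  # perimeter); the biases cancel in the apical/basal ratio
  expect_lt(abs(walls$apical_um2 - 196) / 196, 0.15)
  expect_lt(abs(walls$basal_um2 - 196) / 196, 0.15)
  expect_lt(abs(walls$ratio - 1), 0.1)
})

test_that("trapezoidal cells report their apical/basal wall ratio", {
  vol <- frustum_volume(w_top = 10L, w_bot = 7L, height = 10L)
  g <- build_adjacency(vol)
  ann <- list(central_l2 = 2L, central_l3 = 3L,
              layers = stats::setNames(c("L1", "L2", "L3"),
                                       c("1", "2", "3")),
              graph = g)
  walls <- apical_basal_walls(vol, ann)
  truth <- (21 / 15)^2    # top width 21 voxels vs bottom 15
  expect_lt(abs(walls$ratio - truth) / truth, 0.15)
})

test_that("junction angles detect wall continuity and lateral offsets", {
  flat <- stacked_boxes(side = 20L)
  g <- build_adjacency(flat)
  ja <- junction_wall_angle(flat, g, 2L, 1L, 4)
  expect_gte(ja$mean_angle_deg, 178)

  angles <- vapply(c(2L, 4L, 6L), function(off) {  # 10/20/30% of 20
    vol <- stacked_boxes(side = 20L, offset = off)
    gg <- build_adjacency(vol)
    junction_wall_angle(vol, gg, 2L, 1L, 4)$mean_angle_deg
  }, numeric(1))
  expect_true(all(diff(angles) < 0))
  expect_lt(angles[3], 165)

  # no qualifying side context -> undefined
  iso <- stacked_boxes(side = 4L)
  gi <- build_adjacency(iso)
  expect_error(junction_wall_angle(iso, gi, 2L, 1L, min_side_area = 1e5),
               "undefined")
})

test_that("interface areas add up to the cell surface area", {
  gen <- test_dome(rng_seed = 3)
  vol <- gen$volume
  central <- gen$truth$meta$central_label
  g <- build_adjacency(vol)
  nbs <- primordium3d:::cell_neighbors(g, central, include_exterior = FALSE)
  total <- extract_cell_mesh(vol, central)$area_um2
  parts <- sum(vapply(nbs, function(nb)
    interface_mesh(vol, central, nb)$area_um2, numeric(1)))
  # the central cell has no exterior patch; interfaces must tile its surface
  expect_lt(abs(parts - total) / total, 0.05)
})
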