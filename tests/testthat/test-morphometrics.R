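test_that("volumes are exact voxel counts and conserved over a tessellation", {
  vol <- box_volume(10, 10, 10)
  expect_equal(measure_volume(vol, 1L), 1000)
  expect_error(measure_volume(vol, 99L), "not present")

  ball <- ball_volume(20, voxel_size = c(0.5, 0.5, 0.5))  # r = 10 um
  analytic <- 4 / 3 * pi * 10^3
  expect_lt(abs(measure_volume(ball, 1L) - analytic) / analytic, 0.02)

  gen <- test_dome(rng_seed = 3)
  per_cell <- vapply(cell_labels(gen$volume), function(l)
    measure_volume(gen$volume, l), numeric(1))
  expect_equal(sum(per_cell), foreground_volume(gen$volume))
})

test_that("cell surface meshes reproduce analytic areas", {
  ball <- ball_volume(20)
  mb <- extract_cell_mesh(ball, 1L)
  expect_lt(abs(mb$area_um2 - 4 * pi * 400) / (4 * pi * 400), 0.03)

  cube <- box_volume(20, 20, 20)
  mc <- extract_cell_mesh(cube, 1L)
  expect_lt(abs(mc$area_um2 - 2400) / 2400, 0.05)
  expect_gt(nrow(mc$mesh$vertices), 0)
  expect_true(all(is.finite(mc$mesh$vertices)))
})

test_that("ellipsoid fits recover box axes, sphere symmetry and rotations", {
  # solid box 10 x 20 x 40 um: normalized axes exactly 1:2:4 / 7
  lab <- array(0L, c(44, 24, 14))
  lab[3:42, 3:22, 3:12] <- 1L
  vol <- labeled_volume(lab, c(1, 1, 1))
  fit <- fit_ellipsoid(vol, 1L)
  expect_lt(max(abs(fit$norm_axes - c(1, 2, 4) / 7)), 0.01)

  ball <- ball_volume(15)
  fb <- fit_ellipsoid(ball, 1L)
  expect_lt(max(abs(fb$norm_axes - 1 / 3)), 0.02)
  expect_lt(abs(fb$two_axis_anisotropy - 0.5), 0.02)

  # rotating a box about z leaves the semi-axes unchanged within 3%
  m0 <- ellipsoid_mask(6, 12, 20)
  m30 <- ellipsoid_mask(6, 12, 20, rot = rotation_z(30))
  v0 <- labeled_volume(array(as.integer(m0), dim(m0)), c(1, 1, 1))
  v30 <- labeled_volume(array(as.integer(m30), dim(m30)), c(1, 1, 1))
  s0 <- fit_ellipsoid(v0, 1L)$semi_axes
  s30 <- fit_ellipsoid(v30, 1L)$semi_axes
  expect_lt(max(abs(s0 - s30) / s0), 0.03)
  # and the recovered semi-axes match the construction
  expect_lt(max(abs(s0 - c(6, 12, 20)) / c(6, 12, 20)), 0.05)

  expect_error(fit_ellipsoid(box_volume(1, 8, 8), 1L), "coplanar|27")
})

test_that("shape descriptors follow their closed forms", {
  vs <- 0.4                                  # 20 um cube, 0.4 um voxels
  side <- as.integer(round(20 / vs))
  lab04 <- array(0L, rep(side + 6L, 3))
  lab04[4:(side + 3), 4:(side + 3), 4:(side + 3)] <- 1L
  cube <- labeled_volume(lab04, rep(vs, 3))
  area <- extract_cell_mesh(cube, 1L)$area_um2
  sh <- shape_descriptors(8000, area, fit_ellipsoid(cube, 1L))
  expect_lt(abs(sh$sphericity - (pi / 6)^(1 / 3)), 0.02)

  rugby <- shape_descriptors(1, 1, c(10, 10, 30))
  expect_equal(rugby$prolate_ellipticity, 2 / 3, tolerance = 1e-12)
  expect_equal(rugby$oblate_ellipticity, 0, tolerance = 1e-12)
  disk <- shape_descriptors(1, 1, c(10, 30, 30))
  expect_equal(disk$prolate_ellipticity, 0, tolerance = 1e-12)
  expect_equal(disk$oblate_ellipticity, 2 / 3, tolerance = 1e-12)
})

test_that("sphericity respects the isoperimetric bound and stretch order", {
  shapes <- list(c(10, 10, 10), c(10, 10, 20), c(10, 10, 40), c(5, 5, 40))
  psi <- vapply(shapes, function(s) {
    m <- ellipsoid_mask(s[1], s[2], s[3])
    v <- labeled_volume(array(as.integer(m), dim(m)), c(1, 1, 1))
    mes <- extract_cell_mesh(v, 1L)
    shape_descriptors(measure_volume(v, 1L), mes$area_um2,
                      fit_ellipsoid(v, 1L))$sphericity
  }, numeric(1))
  expect_true(all(psi <= 1.02))
  expect_true(all(diff(psi) < 0))
})

test_that("measure_cells covers every cell and is deterministic", {
  gen <- test_dome(rng_seed = 3, target = 1500)
  ann <- annotate_ovule(gen$volume)
  tab <- measure_cells(gen$volume, ann, ovule_id = "t1")
  expect_equal(nrow(tab), length(cell_labels(gen$volume)))
  central <- tab[tab$contact_class == "central_L2", ]
  expect_lt(abs(central$volume_um3 - 1500) / 1500, 0.15)
  tab2 <- measure_cells(gen$volume, ann, ovule_id = "t1")
  expect_identical(tab, tab2)
})
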