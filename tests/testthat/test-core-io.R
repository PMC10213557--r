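test_that("labeled volumes round-trip through TIFF and NRRD", {
  set.seed(1)
  lab <- array(sample(0:7, 1000, replace = TRUE), c(10, 10, 10))
  vol <- labeled_volume(lab, c(1, 1, 1))

  tif <- withr::local_tempfile(fileext = ".tif")
  write_labeled_volume(vol, tif)
  back <- read_labeled_volume(tif, voxel_size = c(1, 1, 1))
  expect_identical(back$labels, vol$labels)

  # NRRD carries the voxel spacing in its header
  nrrd <- withr::local_tempfile(fileext = ".nrrd")
  vol03 <- labeled_volume(lab, c(0.3, 0.3, 0.3))
  write_labeled_volume(vol03, nrrd)
  back2 <- read_labeled_volume(nrrd)
  expect_identical(back2$labels, vol03$labels)
  expect_equal(back2$voxel_size, c(0.3, 0.3, 0.3))
})

test_that("reading guards against missing metadata and wrong pixel types", {
  tif <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(64), 8, 8), tif, bits.per.sample = 32L)
  expect_error(read_labeled_volume(tif, voxel_size = c(1, 1, 1)),
               "integer")
  lab <- array(1L, c(4, 4, 4))
  ok <- withr::local_tempfile(fileext = ".tif")
  write_labeled_volume(labeled_volume(lab, c(1, 1, 1)), ok)
  expect_error(read_labeled_volume(ok), "voxel size")
  expect_error(labeled_volume(array(-1L, c(2, 2, 2)), c(1, 1, 1)))
  expect_error(labeled_volume(array(1L, c(2, 2, 2)), c(1, 0, 1)))
})

test_that("cell tables round-trip losslessly and reject schema violations", {
  tab <- empty_cell_table()
  row <- tibble::tibble(
    ovule_id = "ov1", cell_label = 1L, layer = "L2",
    contact_class = "central_L2", volume_um3 = exp(1) * 1000,
    semi_axis_a = pi, semi_axis_b = 4.1, semi_axis_c = 9.33333333333311,
    norm_axis_a = NA_real_, norm_axis_b = NA_real_, norm_axis_c = NA_real_,
    two_axis_anisotropy = 0.7, sphericity = 0.91,
    prolate_ellipticity = 0.1, oblate_ellipticity = 0.05,
    surface_area_um2 = 1234.56789012345, apical_wall_area_um2 = 100,
    basal_wall_area_um2 = 50, stage = 2L)
  tab3 <- dplyr::bind_rows(row, dplyr::mutate(row, cell_label = 2L),
                           dplyr::mutate(row, cell_label = 3L))
  # normalized axes must sum to one
  tab3$norm_axis_a <- 0.2; tab3$norm_axis_b <- 0.3; tab3$norm_axis_c <- 0.5
  path <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(tab3, path)
  back <- read_cell_table(path)
  expect_equal(back$volume_um3, tab3$volume_um3, tolerance = 0)
  expect_equal(back$surface_area_um2, tab3$surface_area_um2, tolerance = 0)
  expect_identical(back$cell_label, tab3$cell_label)

  bad <- tab3
  bad$semi_axis_a[2] <- 100  # a > b
  expect_error(write_cell_table(bad, path), "semi_axis")

  # empty table: valid file with header only
  write_cell_table(tab, path)
  expect_equal(nrow(read_cell_table(path)), 0L)
})

test_that("meshes round-trip through OBJ and PLY with scalar channels", {
  # regular icosahedron
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mesh <- surface_mesh(v, f)
  obj <- withr::local_tempfile(fileext = ".obj")
  export_mesh(mesh, obj)
  back <- import_mesh(obj)
  expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-6)
  expect_identical(back$triangles, mesh$triangles)

  ply <- withr::local_tempfile(fileext = ".ply")
  curv <- seq_len(nrow(v)) / 10
  export_mesh(mesh, ply, scalar = curv)
  back2 <- import_mesh(ply)
  expect_lt(max(abs(back2$vertices - mesh$vertices)), 1e-6)
  expect_equal(back2$scalar, curv, tolerance = 1e-6)

  expect_error(surface_mesh(v, rbind(f, c(1, 2, 99))), "out of range")
  expect_error(export_mesh(mesh, ply, scalar = 1:3), "length")
})

test_that("configuration rejects unknown keys and round-trips via YAML", {
  cfg <- default_config(continuity_threshold_deg = 150)
  expect_equal(cfg$continuity_threshold_deg, 150)
  expect_error(default_config(not_a_key = 1), "unknown config")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))
})
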