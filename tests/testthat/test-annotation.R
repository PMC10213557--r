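test_that("adjacency edges carry exact face-count areas", {
  vol <- stacked_boxes(side = 20L)
  g <- build_adjacency(vol, min_contact_area = 1)
  expect_equal(contact_area(g, 1, 2), 400)          # 20 x 20 voxel faces
  expect_equal(contact_area(g, 1, 2), contact_area(g, 2, 1))
  # a single-voxel-face contact is dropped below the threshold
  lab <- array(0L, c(4, 5, 5))
  lab[2, 2:3, 2:3] <- 1L
  lab[3, 3, 3] <- 2L                                 # 1 um^2 contact
  v2 <- labeled_volume(lab, c(1, 1, 1))
  g2 <- build_adjacency(v2, min_contact_area = 2)
  expect_equal(contact_area(g2, 1, 2), 0)
  g3 <- build_adjacency(v2, min_contact_area = 0.5)
  expect_equal(contact_area(g3, 1, 2), 1)
})

test_that("layers are read off the exterior-distance structure", {
  vol <- slab_stack()
  g <- build_adjacency(vol)
  layers <- assign_layers(g)
  expect_equal(unname(layers[c("1", "2", "3")]), c("L1", "L2", "L3"))
})

test_that("the base plane does not count as exterior", {
  # one cell only touching the z-min face, wrapped elsewhere by another
  lab <- array(0L, c(6, 8, 8))
  lab[1:5, 2:7, 2:7] <- 1L
  lab[1:2, 4:5, 4:5] <- 2L     # touches only the base plane face
  vol <- labeled_volume(lab, c(1, 1, 1))
  layers <- assign_layers(build_adjacency(vol))
  expect_equal(unname(layers["2"]), "L2")
})

test_that("contact degrees are breadth-first distances truncated at two", {
  # chain of four boxes A-B-C-D
  lab <- array(0L, c(6, 6, 22))
  for (q in 1:4) lab[2:5, 2:5, (2 + 5 * (q - 1)):(5 * q + 1)] <- q
  vol <- labeled_volume(lab, c(1, 1, 1))
  g <- build_adjacency(vol)
  cls <- assign_contact_degrees(g, 1L)
  expect_equal(unname(cls[c("1", "2", "3", "4")]),
               c("central_L2", "contact1", "contact2", "contact_gt2"))
  # agrees with an independent shortest-path computation
  gg <- igraph::delete_vertices(g$graph, "EXTERIOR")
  d <- igraph::distances(gg, v = "1")[1, c("2", "3", "4")]
  expect_equal(unname(d), c(1, 2, 3))
})

test_that("annotation is equivariant under label permutation", {
  gen <- test_dome(rng_seed = 11)
  vol <- gen$volume
  labs <- cell_labels(vol)
  set.seed(1)
  perm <- sample(labs)
  map <- stats::setNames(perm, labs)
  relab <- vol$labels
  nz <- relab > 0L
  relab[nz] <- map[as.character(vol$labels[nz])]
  vol2 <- labeled_volume(relab, vol$voxel_size)
  ann1 <- annotate_ovule(vol)
  ann2 <- annotate_ovule(vol2)
  expect_equal(unname(map[as.character(ann1$central_l2)]), ann2$central_l2)
  expect_equal(unname(ann1$layers[as.character(labs)]),
               unname(ann2$layers[as.character(map[as.character(labs)])]))
})

test_that("central L2 identification recovers the planted apex cell", {
  hits <- vapply(c(3, 7, 11, 13), function(sd) {
    gen <- test_dome(rng_seed = sd)
    ann <- annotate_ovule(gen$volume)
    ann$central_l2 == gen$truth$meta$central_label
  }, logical(1))
  expect_true(all(hits))
})

test_that("central L2 tie-break prefers the on-axis candidate", {
  # three enclosed L2 cells at equal height under one epidermal wrap; the
  # middle one sits on the axis (the centroid of the L2 cloud)
  lab <- array(0L, c(10, 12, 20))
  lab[1:9, 2:11, 2:19] <- 1L                     # epidermal wrap (L1)
  lab[1:5, 4:9, 4:8] <- 2L                       # off-axis L2
  lab[1:5, 4:9, 9:11] <- 3L                      # on-axis L2 (narrow)
  lab[1:5, 4:9, 12:16] <- 4L                     # off-axis L2
  vol <- labeled_volume(lab, c(1, 1, 1))
  g <- build_adjacency(vol)
  layers <- assign_layers(g)
  central <- identify_central_l2(vol, layers, g, apical_axis = c(0, 0, 1))
  expect_equal(central, 3L)
})

test_that("stack cell selection follows the basal-ward cell axis", {
  gen <- test_dome(rng_seed = 7, target = 1200)
  pd <- plant_division(gen$volume, gen$truth, gen$truth$meta$central_label,
                       "periclinal", f = 0.5, jitter = 0, rng_seed = 2)
  ann <- annotate_ovule(pd$volume)
  expect_equal(ann$central_l3, unname(pd$labels["basal"]))
  # single candidate is selected regardless of angle
  vol <- slab_stack()
  g <- build_adjacency(vol)
  layers <- assign_layers(g)
  sel <- select_central_l3(g, vol, 2L, layers, major_axis = c(1, 0, 0))
  expect_equal(sel, 3L)
})
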