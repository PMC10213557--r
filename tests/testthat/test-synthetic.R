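test_that("dome voxelization matches the analytic half-ball volume", {
  gen <- generate_dome_tessellation(
    H = 20, Rx = 20, Ry = 20, squareness = 2,
    layer_thicknesses = c(4, 5, 5), seeds_per_layer = c(20, 8, 5, 3),
    central_l2_target_volume = 400, voxel_size = c(1, 1, 1), rng_seed = 1)
  analytic <- 2 / 3 * pi * 20^3
  expect_lt(abs(foreground_volume(gen$volume) - analytic) / analytic, 0.05)
})

test_that("tessellation is a partition and is deterministic in the seed", {
  gen <- test_dome(rng_seed = 5)
  vol <- gen$volume
  # every foreground voxel belongs to exactly one cell
  per_cell <- vapply(cell_labels(vol), function(l)
    measure_volume(vol, l), numeric(1))
  expect_equal(sum(per_cell), foreground_volume(vol))
  gen2 <- test_dome(rng_seed = 5)
  expect_identical(gen2$volume$labels, vol$labels)
  gen3 <- test_dome(rng_seed = 6)
  expect_false(identical(gen3$volume$labels, vol$labels))
})

test_that("central cell volume tuning hits its target within tolerance", {
  for (target in c(500, 1500)) {
    gen <- test_dome(rng_seed = 3, target = target)
    attained <- measure_volume(gen$volume, gen$truth$meta$central_label)
    expect_lt(abs(attained - target) / target, 0.15)
  }
  # infeasible target errors with the attained volume in the message
  expect_error(
    generate_dome_tessellation(
      H = 15, Rx = 10, Ry = 10, layer_thicknesses = c(3, 4, 4),
      seeds_per_layer = c(10, 5, 3, 2), central_l2_target_volume = 1e5,
      rng_seed = 1),
    "attained")
})

test_that("planted mid-plane divisions produce balanced daughters", {
  # a flat mid-plane through a symmetric convex cell splits it evenly:
  # anticlinal split of a digital ball (periclinal splits follow the curved
  # depth surface, where balance is set by the split fraction instead)
  ballv <- ball_volume(10)
  truth0 <- structure(list(
    cells = tibble::tibble(cell_label = 1L, layer = "L2",
                           contact_class = "other", divided = FALSE,
                           orientation = NA_character_, plane_nx = NA_real_,
                           plane_ny = NA_real_, plane_nz = NA_real_,
                           offset_fraction = NA_real_, jitter_um = NA_real_,
                           sibling = NA_integer_),
    meta = list(central_label = -1L, central_l3_label = NA_integer_,
                layer_thicknesses = c(4, 4, 4))), class = "ovule_truth")
  pd0 <- plant_division(ballv, truth0, 1L, "anticlinal", f = 0.5,
                        jitter = 0, rng_seed = 2)
  v1 <- measure_volume(pd0$volume, pd0$labels[1])
  v2 <- measure_volume(pd0$volume, pd0$labels[2])
  expect_lte(max(v1, v2) / min(v1, v2), 1.15)
  gen <- test_dome(rng_seed = 7, target = 1200)
  pd <- plant_division(gen$volume, gen$truth, gen$truth$meta$central_label,
                       "periclinal", f = 0.5, jitter = 0, rng_seed = 2)
  # stored plane normal is the local radial direction for periclinal splits
  tr <- pd$truth$cells[pd$truth$cells$cell_label == pd$labels["apical"], ]
  expect_true(tr$divided)
  nrm <- c(tr$plane_nx, tr$plane_ny, tr$plane_nz)
  d2 <- primordium3d:::exterior_distance(gen$volume)
  ctr <- colMeans(cell_coords(gen$volume, gen$truth$meta$central_label))
  rad <- primordium3d:::radial_direction(d2, c(1, 1, 1), ctr)
  expect_lt(op_angle(nrm, rad), 10)
})

test_that("zero jitter keeps daughter walls continuous; jitter breaks them", {
  gen <- test_dome(rng_seed = 7, target = 1500)
  angles <- vapply(c(0, 2, 5), function(jit) {
    pd <- plant_division(gen$volume, gen$truth,
                         gen$truth$meta$central_label, "periclinal",
                         f = 0.5, jitter = jit, rng_seed = 4)
    ann <- annotate_ovule(pd$volume)
    junction_wall_angle(pd$volume, ann$graph, pd$labels["apical"],
                        pd$labels["basal"], 4)$mean_angle_deg
  }, numeric(1))
  # walls are coplanar by construction at jitter 0, but the power-diagram
  # facets of dome cells carry a few degrees of intrinsic curvature, so the
  # strict >= 178 reading belongs to planar fixtures (see the stacked-box
  # tests); here the angle must sit clearly above the 160-degree threshold
  # and fall monotonically with jitter
  expect_gte(angles[1], 170)
  expect_true(all(diff(angles) < 0))
  expect_lt(angles[3], 165)
})

test_that("degenerate splits are refused", {
  gen <- test_dome(rng_seed = 7)
  expect_error(
    plant_division(gen$volume, gen$truth, gen$truth$meta$central_label,
                   "periclinal", f = 0.02, jitter = 0, rng_seed = 1),
    "degenerate")
})

test_that("cohorts honour per-stage plans including empty stages", {
  sp <- default_stage_params(c(2, 0, 0, 1))
  coh <- generate_cohort(sp, rng_seed = 9)
  expect_length(coh, 3L)
  stages <- vapply(coh, function(o) o$truth$meta$stage, integer(1))
  expect_equal(sort(unique(stages)), c(1L, 4L))
  # planted central volumes follow the stage means
  v1 <- vapply(coh[stages == 1], function(o)
    o$truth$meta$planted_central_volume, numeric(1))
  expect_true(all(v1 > 300 & v1 < 800))
})
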