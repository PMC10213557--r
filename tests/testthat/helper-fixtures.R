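# Fixtures built in code: phantom volumes with known geometry.

# solid axis-aligned box; extents in voxels (z, y, x), 1-voxel background pad
box_volume <- function(nz, ny, nx, voxel_size = c(1, 1, 1), label = 1L) {
  lab <- array(0L, c(nz + 2L, ny + 2L, nx + 2L))
  lab[2:(nz + 1), 2:(ny + 1), 2:(nx + 1)] <- label
  labeled_volume(lab, voxel_size)
}

# digital ball of radius r voxels, centered, in a cube grid
ball_mask <- function(r, pad = 2L) {
  n <- 2L * (r + pad) + 1L
  ax <- seq_len(n) - (n + 1) / 2
  outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= r^2
}

ball_volume <- function(r, voxel_size = c(1, 1, 1)) {
  m <- ball_mask(r)
  labeled_volume(array(as.integer(m), dim(m)), voxel_size)
}

# Two boxes stacked along z (labels 1 below, 2 above); `offset` shifts the
# upper box laterally (in both lateral directions, so every side wall shows
# the discontinuity step).
stacked_boxes <- function(side = 20L, offset = 0L, voxel_size = c(1, 1, 1)) {
  nz <- 2L * side + 2L
  nxy <- side + 2L + abs(offset)
  lab <- array(0L, c(nz, nxy, nxy))
  lab[2:(side + 1), 2:(side + 1), 2:(side + 1)] <- 1L
  lab[(side + 2):(2L * side + 1), (2L + offset):(side + 1L + offset),
      (2L + offset):(side + 1L + offset)] <- 2L
  labeled_volume(lab, voxel_size)
}

# Nested-shell phantom: label 1 is the outer shell (exterior contact),
# label 2 a shell nested inside it, label 3 the core. The inner labels'
# only other exposure is the base plane (z-min face, not exterior), so the
# exterior-distance layering reads L1/L2/L3 by construction.
slab_stack <- function(side = 12L, thick = 4L) {
  nz <- 3L * thick + 2L
  n <- side + 8L
  lab <- array(0L, c(nz, n, n))
  lab[1:(3 * thick + 1), 2:(n - 1), 2:(n - 1)] <- 1L
  lab[1:(2 * thick), 4:(n - 3), 4:(n - 3)] <- 2L
  lab[1:thick, 6:(n - 5), 6:(n - 5)] <- 3L
  labeled_volume(lab, c(1, 1, 1))
}

# a trapezoidal (frustum) central cell: label 2, between an L1 plate
# (label 1, above) and a basal cell (label 3, below); apical/basal wall
# area ratio set by the top and bottom half-widths
frustum_volume <- function(w_top = 10L, w_bot = 7L, height = 10L,
                           plate = 4L) {
  n <- 2L * max(w_top, w_bot) + 8L
  cz <- (n + 1L) / 2
  nz <- plate * 2L + height + 2L
  lab <- array(0L, c(nz, n, n))
  zc <- function(k) k + 1L  # 1-voxel pad below
  # basal cell (bottom plate), full width of the frustum bottom
  for (k in seq_len(plate))
    lab[zc(k), (cz - w_bot):(cz + w_bot), (cz - w_bot):(cz + w_bot)] <- 3L
  # frustum: width interpolates bottom -> top
  for (k in seq_len(height)) {
    w <- round(w_bot + (w_top - w_bot) * (k - 0.5) / height)
    rng <- (cz - w):(cz + w)
    lab[zc(plate + k), rng, rng] <- 2L
  }
  # apical plate (epidermis), covering the frustum top
  for (k in seq_len(plate))
    lab[zc(plate + height + k),
        (cz - w_top - 2):(cz + w_top + 2),
        (cz - w_top - 2):(cz + w_top + 2)] <- 1L
  labeled_volume(lab, c(1, 1, 1))
}

# solid ellipsoid mask with semi-axes (voxels), axis-aligned: a <= b <= c
# along (x, y, z) respectively unless rotated by `rot` (3x3 matrix, applied
# to coordinates)
ellipsoid_mask <- function(a, b, c, rot = NULL, pad = 3L) {
  n <- 2L * ceiling(max(a, b, c)) + 2L * pad + 1L
  ax <- seq_len(n) - (n + 1) / 2
  grid <- expand.grid(z = ax, y = ax, x = ax)
  p <- cbind(grid$x, grid$y, grid$z)
  if (!is.null(rot)) p <- p %*% rot
  inside <- (p[, 1] / a)^2 + (p[, 2] / b)^2 + (p[, 3] / c)^2 <= 1
  array(inside, c(n, n, n))
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# small standard dome used across tests (cheap: ~30k voxels)
test_dome <- function(rng_seed = 7, target = 1000, stack_seed = FALSE) {
  generate_dome_tessellation(
    H = 30, Rx = 22, Ry = 22, squareness = 2.2,
    layer_thicknesses = c(5, 7, 7), seeds_per_layer = c(30, 12, 8, 5),
    central_l2_target_volume = target, voxel_size = c(1, 1, 1),
    rng_seed = rng_seed, central_axial_ratio = 0.7,
    stack_seed = stack_seed)
}
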