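# Shared fixtures: tiny grids, smooth fields, random rotations, and a small
# phantom configuration reused across test files. Everything is generated in
# code; no binary fixtures.

tiny_grid <- function(n = 16, vs = 2) image_grid(rep(n, 3), voxel_size = vs)

# deterministic smooth displacement field (sinusoidal, sub-voxel control)
sinusoid_field <- function(grid, amp = 1.5) {
  pts <- omtemplate:::grid_world_coords(grid)
  d <- amp * cbind(sin(pts[, 1] / 8) * cos(pts[, 2] / 10),
                   sin(pts[, 3] / 9),
                   cos(pts[, 1] / 12) * sin(pts[, 2] / 11))
  displacement_field(grid, d)
}

uniform_translation_field <- function(grid, t) {
  displacement_field(grid, matrix(rep(t, each = prod(grid$shape)), ncol = 3))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# small, fast phantom (32^3 x 3 mm) for module tests; acceptance tests use
# the full 48^3 default
small_phantom_params <- function(...) {
  phantom_params(grid_shape = 32, voxel_size = 3, ...)
}

# quiet phantom: no randomness at all
still_phantom_params <- function(grid_shape = 32) {
  phantom_params(grid_shape = grid_shape, voxel_size = 3,
                 subject_warp_amplitude = 0,
                 affine_jitter = list(rot_deg = 0, scale_dev = 0, trans_mm = 0),
                 noise_sd = list(t1 = 0, flair = 0, dti = 0))
}

in_brain_idx <- function(subj) as.numeric(subj$brain_mask$values) > 0.5

field_mag <- function(field) sqrt(rowSums(matrix(field$disp, ncol = 3)^2))

rel_rms <- function(a, b) {
  av <- as.numeric(a); bv <- as.numeric(b)
  sqrt(mean((av - bv)^2)) / max(sqrt(mean(bv^2)), 1e-12)
}
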