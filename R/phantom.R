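#' Parameters of the synthetic multimodal phantom
#'
#' The phantom emulates, at desk scale, a head with tissue-contrast scalar
#' channels, an anisotropic white-matter tract in the tensor channel,
#' age-dependent ventricle expansion, smooth per-subject random warps, small
#' random affine misalignment, and additive noise. Ground-truth maps to
#' canonical space are retained exactly.
#'
#' @param grid_shape voxels per axis (cubic), default 48.
#' @param voxel_size voxel edge in mm, default 3.
#' @param ventricle_age_slope fractional ventricle radius growth per year of
#'   age (default 0.012, i.e. about +1.2 % radius/year, giving a few percent
#'   volume change per year as seen in ageing cohorts).
#' @param reference_age age (years) at which ventricles have canonical size.
#' @param subject_warp_amplitude 95th percentile of the random warp magnitude
#'   in mm (default 4).
#' @param subject_warp_smoothness Gaussian smoothing length of the random
#'   warp in mm (default 12).
#' @param affine_jitter list with `rot_deg`, `scale_dev`, `trans_mm` maxima
#'   for the random affine misalignment.
#' @param noise_sd named list of additive channel noise (t1/flair on the
#'   raw intensity scale, dti on tensor components).
#' @param seed base seed for cohort generation.
#' @return `PhantomParams` list.
#' @export
phantom_params <- function(grid_shape = 48, voxel_size = 3,
                           ventricle_age_slope = 0.012,
                           reference_age = 52.5,
                           subject_warp_amplitude = 4,
                           subject_warp_smoothness = 12,
                           affine_jitter = list(rot_deg = 3, scale_dev = 0.03,
                                                trans_mm = 3),
                           noise_sd = list(t1 = 10, flair = 10, dti = 1e-5),
                           seed = 1L) {
  stopifnot(subject_warp_amplitude >= 0, subject_warp_smoothness > 0,
            ventricle_age_slope >= 0 || TRUE)
  p <- list(grid_shape = rep(as.integer(grid_shape), length.out = 3),
            voxel_size = voxel_size,
            ventricle_age_slope = ventricle_age_slope,
            reference_age = reference_age,
            subject_warp_amplitude = subject_warp_amplitude,
            subject_warp_smoothness = subject_warp_smoothness,
            affine_jitter = affine_jitter,
            noise_sd = noise_sd,
            seed = as.integer(seed))
  # geometry scales with the grid so the head keeps a >= 2 voxel margin
  fov <- min(p$grid_shape) * voxel_size
  # sized so that the whole nonzero-intensity support (head plus sigmoid
  # shoulder down to the background clip) stays strictly inside the grid
  p$head_radius <- 0.36 * fov
  if (p$head_radius + 2 * voxel_size > fov / 2)
    stop("phantom head does not fit the grid with a 2-voxel margin")
  class(p) <- "PhantomParams"
  p
}

# --- canonical anatomy -----------------------------------------------------

# Soft (sigmoid) indicator of r <= r0 with edge width w (mm)
soft_in <- function(r, r0, w) 1 / (1 + exp((r - r0) / w))

phantom_geometry <- function(params) {
  R <- params$head_radius
  list(
    head_r = R,                 # scalp outer radius
    skull_r = 0.92 * R,         # inner scalp / outer skull
    brain_r = 0.82 * R,         # brain (GM) outer
    wm_r = 0.62 * R,            # WM outer
    # centres far enough apart that the age-deformation supports (3.2x the
    # semi-axes) of the two ventricles never overlap
    vent_c = rbind(c(-0.28, 0.05, 0.05) * R, c(0.28, 0.05, 0.05) * R),
    vent_semi = c(0.08, 0.14, 0.11) * R,   # ellipsoid semi-axes
    tract_centre = c(0, -0.05 * R, -0.05 * R),
    tract_r = 0.40 * R,         # radius of the C-shaped arc (in y-z plane)
    tract_tube = 0.14 * R       # tube radius (~2.4 voxels at desk scale, resolvable)
  )
}

# anisotropic eigenvalues giving FA ~ 0.7 (units mm^2/s)
TRACT_EVALS <- c(1.5e-3, 0.35e-3, 0.35e-3)
ISO_WM_D <- 0.7e-3
ISO_CSF_D <- 3.0e-3

#' Deterministic canonical phantom anatomy
#'
#' Builds the canonical head: bright scalp shell, dark skull gap, GM shell,
#' WM interior and two mirrored ellipsoidal ventricles in the scalar
#' channels; cigar-shaped tensors (FA about 0.7) following the tangent of a
#' C-shaped arc in the WM and isotropic tensors elsewhere in the brain.
#' Ground-truth maps are the identity.
#'
#' @param params `PhantomParams`.
#' @return `SyntheticSubject` list (id, age, t1, flair, dti, brain_mask,
#'   truth_warp_to_canonical, truth_affine).
#' @export
make_canonical_anatomy <- function(params) {
  grid <- image_grid(params$grid_shape, voxel_size = params$voxel_size)
  pts <- grid_world_coords(grid)
  img <- phantom_intensities(pts, params)
  dti <- phantom_tensors(pts, params)
  subj <- list(id = "canonical", age = params$reference_age,
               t1 = scalar_image(grid, img$t1),
               flair = scalar_image(grid, img$flair),
               dti = tensor_image(grid, dti$tensors, valid = dti$valid),
               brain_mask = scalar_image(grid, img$brain_mask),
               truth_warp_to_canonical = zero_field(grid),
               truth_affine = affine_identity())
  class(subj) <- "SyntheticSubject"
  subj
}

# Scalar channel intensities at world points (rows of pts), canonical space.
# Vent scale s enlarges the ventricles (evaluated in canonical coordinates
# the caller already mapped into).
phantom_intensities <- function(pts, params, vent_scale = 1) {
  geo <- phantom_geometry(params)
  w <- 0.6 * params$voxel_size          # soft edge width, mm
  r <- sqrt(rowSums(pts^2))
  head <- soft_in(r, geo$head_r, w)
  skull <- soft_in(r, geo$skull_r, w)
  brain <- soft_in(r, geo$brain_r, w)
  wm <- soft_in(r, geo$wm_r, w)
  vent <- phantom_vent_frac(pts, params, vent_scale, w)
  # T1: scalp bright, skull dark, GM mid, WM bright, CSF dark
  t1 <- 950 * (head - skull) + 100 * (skull - brain) +
    500 * (brain - wm) + 800 * (wm - vent * wm) + 150 * vent * wm
  # FLAIR: scalp mid, skull dark, GM bright, WM mid, CSF suppressed (dark)
  flair <- 400 * (head - skull) + 80 * (skull - brain) +
    750 * (brain - wm) + 450 * (wm - vent * wm) + 60 * vent * wm
  # clip the sigmoid tails to exact zero: background is true zero with a
  # deliberate intensity gap below the dimmest tissue (~60), so that the
  # nonbackground definition used for intensity normalisation is stable
  # under resampling (interpolation ripple at the clip edge stays < ~5)
  t1 <- ifelse(t1 < 20, 0, t1)
  flair <- ifelse(flair < 20, 0, flair)
  list(t1 = t1, flair = flair,
       brain_mask = as.numeric(brain > 0.5))
}

# soft fraction inside either (possibly scaled) ventricle ellipsoid
phantom_vent_frac <- function(pts, params, vent_scale, w) {
  geo <- phantom_geometry(params)
  out <- numeric(nrow(pts))
  for (i in 1:2) {
    d <- sweep(pts, 2, geo$vent_c[i, ])
    # ellipsoidal "radius" normalised so the boundary sits at rho = rho0
    rho <- sqrt(rowSums(sweep(d, 2, geo$vent_semi, `/`)^2))
    out <- pmax(out, soft_in(rho, vent_scale, w / mean(geo$vent_semi)))
  }
  out
}

# Tensor channel at world points: tract tangent cigars within a C-arc tube,
# isotropic elsewhere inside the brain, invalid outside.
phantom_tensors <- function(pts, params, vent_scale = 1) {
  geo <- phantom_geometry(params)
  r <- sqrt(rowSums(pts^2))
  inbrain <- r <= geo$brain_r
  vent <- phantom_vent_frac(pts, params, vent_scale, 0.3 * params$voxel_size) > 0.5
  # C-shaped arc: circle of radius tract_r in the y-z plane about tract_centre,
  # restricted to an open angular range; tube distance decides membership
  d <- sweep(pts, 2, geo$tract_centre)
  rho_yz <- sqrt(d[, 2]^2 + d[, 3]^2)
  theta <- atan2(d[, 3], d[, 2])
  in_arc <- theta > -2.2 & theta < 2.2         # "C" opening
  dist_tube <- sqrt((rho_yz - geo$tract_r)^2 + d[, 1]^2)
  tract <- inbrain & !vent & in_arc & dist_tube <= geo$tract_tube
  n <- nrow(pts)
  tens <- matrix(0, n, 6)
  iso <- inbrain & !tract
  dval <- ifelse(vent, ISO_CSF_D, ISO_WM_D)
  tens[iso, 1] <- dval[iso]; tens[iso, 4] <- dval[iso]; tens[iso, 6] <- dval[iso]
  ti <- which(tract)
  if (length(ti)) {
    # tangent of the arc at the nearest arc point: e_theta in the y-z plane
    tx <- rep(0, length(ti))
    ty <- -sin(theta[ti])
    tz <- cos(theta[ti])
    l1 <- TRACT_EVALS[1]; lp <- TRACT_EVALS[2]
    # D = lp I + (l1 - lp) t t^T
    tens[ti, 1] <- lp + (l1 - lp) * tx^2
    tens[ti, 2] <- (l1 - lp) * tx * ty
    tens[ti, 3] <- (l1 - lp) * tx * tz
    tens[ti, 4] <- lp + (l1 - lp) * ty^2
    tens[ti, 5] <- (l1 - lp) * ty * tz
    tens[ti, 6] <- lp + (l1 - lp) * tz^2
  }
  list(tensors = tens, valid = inbrain)
}

# --- ground-truth deformations --------------------------------------------

# Age map g_age: aged space -> canonical space. Inside a ventricle's support
# the point contracts about the ventricle centre by 1/s (so the aged
# ventricle, s times larger, maps onto the canonical one); the effect tapers
# smoothly to zero by 2.2x the ventricle extent. Applied analytically.
age_map_points <- function(pts, params, s) {
  if (abs(s - 1) < 1e-12) return(pts)
  geo <- phantom_geometry(params)
  out <- pts
  for (i in 1:2) {
    d <- sweep(out, 2, geo$vent_c[i, ])
    rho <- sqrt(rowSums(sweep(d, 2, geo$vent_semi, `/`)^2))
    # radial profile: full contraction out to a margin beyond the ventricle
    # boundary (so the scaling is exactly uniform across the ventricle and
    # any finite-difference stencil), then a smooth taper to 0 by Rout; the
    # wide shell keeps the deformation well resolved on a 3 mm grid
    Rout <- 3.2
    core <- s + 0.7
    tfrac <- pmin(pmax((Rout - rho) / (Rout - core), 0), 1)
    tfrac <- tfrac^2 * (3 - 2 * tfrac)          # smoothstep
    scale_local <- 1 + (1 / s - 1) * tfrac
    out <- sweep(d * scale_local, 2, geo$vent_c[i, ], `+`)
  }
  out
}

ventricle_scale <- function(params, age) {
  1 + params$ventricle_age_slope * (age - params$reference_age)
}

# Smooth random displacement field: Gaussian-filtered white noise rescaled so
# the 95th percentile of |d| equals the requested amplitude.
random_smooth_field <- function(grid, amplitude, smoothness_mm, seed) {
  if (amplitude <= 0) return(zero_field(grid))
  set.seed(seed)
  s <- grid$shape
  vs <- mean(grid_voxel_size(grid))
  sigma_vox <- smoothness_mm / vs
  d <- array(0, dim = c(s, 3L))
  for (k in 1:3) d[, , , k] <- gauss_smooth3(array(rnorm(prod(s)), s), sigma_vox)
  mag <- sqrt(rowSums(matrix(d, ncol = 3)^2))
  q <- quantile(mag, 0.95, names = FALSE)
  if (q > 0) d <- d * (amplitude / q)
  displacement_field(grid, d)
}

# separable Gaussian smoothing of a 3-D array (truncated at 3 sigma,
# zero-padded boundary, kernel normalised)
gauss_smooth3 <- function(v, sigma_vox) {
  if (sigma_vox <= 0) return(v)
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-half):half)^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  for (axis in 1:3) v <- conv_axis(v, k, axis)
  v
}

conv_axis <- function(v, k, axis) {
  s <- dim(v)
  half <- (length(k) - 1L) %/% 2L
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  vp <- aperm(v, perm)
  m <- matrix(vp, nrow = dim(vp)[1])
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    off <- j - half - 1L
    src <- seq_len(n) + off
    okk <- src >= 1L & src <= n
    out[okk, ] <- out[okk, ] + k[j] * m[src[okk], ]
  }
  vp <- array(out, dim = dim(vp))
  aperm(vp, order(perm))
}

# FWHM (mm) -> Gaussian sigma (mm)
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Smooth a scalar image with a Gaussian kernel
#' @param img `ScalarImage`.
#' @param fwhm_mm kernel full width at half maximum in mm (0 = no-op).
#' @export
smooth_image <- function(img, fwhm_mm) {
  if (fwhm_mm <= 0) return(img)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / mean(grid_voxel_size(img$grid))
  scalar_image(img$grid, gauss_smooth3(img$values, sigma_vox))
}

# small random affine (subject space -> jittered space), rotations about the
# origin (grid centre)
random_jitter_affine <- function(jit, seed) {
  set.seed(seed)
  ang <- runif(3, -jit$rot_deg, jit$rot_deg) * pi / 180
  sc <- 1 + runif(3, -jit$scale_dev, jit$scale_dev)
  tr <- runif(3, -jit$trans_mm, jit$trans_mm)
  Rx <- rot3(1, ang[1]); Ry <- rot3(2, ang[2]); Rz <- rot3(3, ang[3])
  L <- Rz %*% Ry %*% Rx %*% diag(sc)
  M <- diag(4); M[1:3, 1:3] <- L; M[1:3, 4] <- tr
  affine_transform(M, "affine12")
}

rot3 <- function(axis, a) {
  c3 <- cos(a); s3 <- sin(a)
  m <- diag(3)
  ij <- setdiff(1:3, axis)
  m[ij[1], ij[1]] <- c3; m[ij[2], ij[2]] <- c3
  m[ij[1], ij[2]] <- -s3; m[ij[2], ij[1]] <- s3
  m
}

#' Generate one synthetic subject
#'
#' The subject is produced by sampling the canonical anatomy through the
#' analytic composite map `m(x) = g_age(h(B x))`: a random small affine `B`
#' (`truth_affine`), a smooth random displacement `h` and the age-dependent
#' ventricle map `g_age` (ventricle radii scaled by
#' `1 + slope * (age - reference_age)`), with additive channel noise.
#' `truth_warp_to_canonical` stores the nonlinear part `g_age o h` on the
#' subject grid; the full generative map is that field composed after `B`.
#' Tensors are reoriented consistently with the map (PPD on the local
#' Jacobian). If the requested deformation is not diffeomorphic the random
#' warp is regenerated at reduced amplitude with a warning.
#'
#' @param params `PhantomParams`.
#' @param age subject age in years.
#' @param subject_seed integer seed for this subject's randomness.
#' @param id subject identifier.
#' @return `SyntheticSubject`.
#' @export
make_subject <- function(params, age, subject_seed, id = sprintf("sub-%05d", subject_seed)) {
  grid <- image_grid(params$grid_shape, voxel_size = params$voxel_size)
  s_age <- ventricle_scale(params, age)
  amp <- params$subject_warp_amplitude
  for (attempt in 1:5) {
    rnd <- random_smooth_field(grid, amp, params$subject_warp_smoothness,
                               seed = subject_seed)
    B <- if (max(unlist(params$affine_jitter)) > 0)
      random_jitter_affine(params$affine_jitter, seed = subject_seed + 7L)
    else affine_identity()
    # nonlinear truth on the subject grid: psi(x) = g_age(x + d_rnd(x)) - x
    x <- grid_world_coords(grid)
    hx <- x + field_disp_matrix(rnd)
    psi <- displacement_field(grid, age_map_points(hx, params, s_age) - x)
    if (amp == 0 || min(jacobian_determinant_map(psi)$values) > 0) break
    warning("non-diffeomorphic phantom warp; reducing amplitude")
    amp <- 0.7 * amp
  }
  # full generative map evaluated analytically (no interpolation):
  # m(x) = g_age(B x + d_rnd(B x)); d_rnd at B x via exact re-evaluation is
  # not available (filtered noise lives on the grid), so d_rnd is evaluated
  # with trilinear interpolation there -- the stored truth composition uses
  # the identical evaluation path.
  xb <- apply_affine_points(B, x)
  m_pts <- xb + eval_field_disp(psi, xb)$disp
  img <- phantom_intensities_at(m_pts, params, s_age)
  set.seed(subject_seed + 13L)
  n <- nrow(m_pts)
  t1v <- pmax(img$t1 + rnorm(n, 0, params$noise_sd$t1), 0)
  flv <- pmax(img$flair + rnorm(n, 0, params$noise_sd$flair), 0)
  # tensors: evaluate canonical tensors at mapped points, reorient by the
  # local map Jacobian (finite differences of the composite map)
  comp <- displacement_field(grid, m_pts - x)
  # the composite map lands in canonical coordinates, where the ventricles
  # have canonical size
  dti <- phantom_tensors(m_pts, params, vent_scale = 1)
  tens <- dti$tensors
  Jr <- warp_jacobian_matrices(comp)
  Minv <- invert3_rows(Jr)
  okv <- dti$valid & Minv$ok
  pp <- ppd_reorient_batch(tens[okv, , drop = FALSE], Minv$inv[okv, , drop = FALSE])
  tens[okv, ] <- pp$tensors
  valid <- okv
  valid[okv][!pp$valid] <- FALSE
  if (params$noise_sd$dti > 0) tens[valid, ] <- tens[valid, ] +
    matrix(rnorm(sum(valid) * 6, 0, params$noise_sd$dti), ncol = 6)
  subj <- list(id = id, age = age,
               t1 = scalar_image(grid, t1v),
               flair = scalar_image(grid, flv),
               dti = tensor_image(grid, tens, valid = array(valid, grid$shape)),
               brain_mask = scalar_image(grid, img$brain_mask),
               truth_warp_to_canonical = psi,
               truth_affine = B)
  class(subj) <- "SyntheticSubject"
  subj
}

# canonical-space intensities sampled at canonical points reached through the
# age map (so vent_scale has already been applied by the map itself)
phantom_intensities_at <- function(pts_canonical, params, s_age) {
  phantom_intensities(pts_canonical, params, vent_scale = 1)
}

#' Generate a synthetic cohort
#'
#' Ages are drawn uniformly in `[age_low, age_high)` (or from a supplied
#' sampler) and per-subject seeds are derived deterministically from `seed`.
#'
#' @param params `PhantomParams`.
#' @param n number of subjects.
#' @param age_low,age_high age range in years.
#' @param seed cohort seed (defaults to `params$seed`).
#' @param age_sampler optional `function(n)` returning ages, to mimic
#'   nonuniform age densities.
#' @return `SyntheticCohort` with `subjects` and `params`.
#' @export
make_cohort <- function(params, n, age_low = 50, age_high = 55,
                        seed = params$seed, age_sampler = NULL) {
  stopifnot(n >= 1, age_low < age_high)
  set.seed(seed)
  ages <- if (is.null(age_sampler)) runif(n, age_low, age_high) else age_sampler(n)
  sseeds <- sample.int(2^30, n)
  subjects <- vector("list", n)
  for (i in seq_len(n))
    subjects[[i]] <- make_subject(params, ages[i], sseeds[i],
                                  id = sprintf("sub-%03d", i))
  structure(list(subjects = subjects, params = params, seed = seed),
            class = "SyntheticCohort")
}

#' Ages of a cohort
#' @param cohort `SyntheticCohort`.
#' @export
cohort_ages <- function(cohort) vapply(cohort$subjects, `[[`, numeric(1), "age")

#' Binary canonical ventricle mask
#' @param params `PhantomParams`.
#' @export
canonical_ventricle_mask <- function(params) {
  grid <- image_grid(params$grid_shape, voxel_size = params$voxel_size)
  pts <- grid_world_coords(grid)
  v <- phantom_vent_frac(pts, params, 1, 0.3 * params$voxel_size)
  scalar_image(grid, as.numeric(v > 0.5))
}
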