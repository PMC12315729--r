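# Affine stage: global-misalignment correction, unbiased midspace, affine
# template, and the mask/weight recipes used by the nonlinear registrations.

#' Matrix logarithm / exponential of 4x4 affines
#'
#' Eigendecomposition-based principal logarithm; transforms with a negative
#' real eigenvalue (no real log) are an error.
#' @param M 4x4 matrix.
#' @export
affine_logm <- function(M) {
  ev <- eigen(M, only.values = TRUE)$values
  if (any(abs(Im(ev)) < 1e-12 & Re(ev) <= 0))
    stop("matrix logarithm undefined: non-positive real eigenvalue")
  # inverse scaling and squaring (robust for defective matrices, e.g. pure
  # translations): repeated Denman-Beavers square roots until close to I,
  # then the Mercator series
  A <- M
  k <- 0L
  while (norm(A - diag(4), "F") > 0.25 && k < 40L) {
    Y <- A; Z <- diag(4)
    for (i in 1:60) {
      Yn <- 0.5 * (Y + solve(Z))
      Zn <- 0.5 * (Z + solve(Y))
      if (max(abs(Yn - Y)) < 1e-14) { Y <- Yn; Z <- Zn; break }
      Y <- Yn; Z <- Zn
    }
    A <- Y
    k <- k + 1L
  }
  X <- A - diag(4)
  L <- matrix(0, 4, 4); P <- diag(4)
  for (i in 1:30) {
    P <- P %*% X
    L <- L + (-1)^(i + 1) / i * P
  }
  L * 2^k
}

#' @rdname affine_logm
#' @export
affine_expm <- function(M) {
  # scaling and squaring with a Taylor series; 4x4 inputs are tiny
  k <- max(0L, ceiling(log2(max(1, norm(M, "F")))))
  A <- M / 2^k
  S <- diag(4); P <- diag(4)
  for (i in 1:16) { P <- P %*% A / i; S <- S + P }
  for (i in seq_len(k)) S <- S %*% S
  S
}

#' Unbiased midspace transforms
#'
#' Given per-subject affines to a common reference, returns transforms to the
#' cohort midspace: `M_n = expm(logm(A_n) - mean_l logm(A_l))`. The matrix-log
#' mean of the outputs is exactly zero, which is the testable statement of an
#' unbiased midspace (no subject's geometry dominates).
#'
#' @param affines list of `AffineTransform`s (>= 2), one per subject.
#' @return list of `AffineTransform`s to the midspace.
#' @export
midspace_transforms <- function(affines) {
  stopifnot(length(affines) >= 2L)
  logs <- lapply(seq_along(affines), function(i) {
    tryCatch(affine_logm(affines[[i]]$matrix),
             error = function(e) stop(sprintf("subject %d: %s", i, conditionMessage(e))))
  })
  mlog <- Reduce(`+`, logs) / length(logs)
  lapply(seq_along(affines), function(i)
    affine_transform(affine_expm(logs[[i]] - mlog), "affine12"))
}

# --- intensity-based affine registration -----------------------------------

affine_from_params <- function(p, dof, centre) {
  ang <- p[4:6]
  Rm <- rot3(3, ang[3]) %*% rot3(2, ang[2]) %*% rot3(1, ang[1])
  L <- Rm
  if (dof == "affine12") {
    sc <- exp(p[7:9])
    sh <- p[10:12]
    Sh <- diag(3); Sh[1, 2] <- sh[1]; Sh[1, 3] <- sh[2]; Sh[2, 3] <- sh[3]
    L <- Rm %*% Sh %*% diag(sc)
  }
  M <- diag(4)
  M[1:3, 1:3] <- L
  # rotate/scale about the volume centre, then translate
  M[1:3, 4] <- p[1:3] + centre - L %*% centre
  affine_transform(M, if (dof == "rigid6") "rigid6" else "affine12")
}

params_dim <- function(dof) if (dof == "rigid6") 6L else 12L

#' Intensity-based affine registration
#'
#' Finds the world-to-world transform `A` (fixed space -> moving space, a
#' pullback resampling map) minimising the mean squared intensity difference
#' between `fixed` and `moving` resampled through `A`, using a smoothed
#' multiresolution pyramid and derivative-free Nelder-Mead optimisation.
#' Deterministic given its inputs.
#'
#' @param moving,fixed `ScalarImage`s with overlapping fields of view.
#' @param dof `"rigid6"` (3 translations + 3 rotations) or `"affine12"`
#'   (+ log-scales and shears).
#' @param fwhm_levels smoothing FWHMs (mm) of the pyramid, coarse to fine.
#' @param maxit Nelder-Mead iteration cap per level.
#' @param stride voxel subsampling stride for the cost evaluation.
#' @param init optional initial `AffineTransform`.
#' @return `AffineTransform` with attribute `"cost"` (final MSE).
#' @export
affine_register <- function(moving, fixed, dof = c("affine12", "rigid6"),
                            fwhm_levels = c(12, 6, 0), maxit = 300,
                            stride = 2L, init = NULL) {
  dof <- match.arg(dof)
  centre <- as.numeric(voxel_to_world_points(
    fixed$grid, matrix((fixed$grid$shape - 1) / 2, 1)))
  p <- numeric(params_dim(dof))
  if (!is.null(init)) {
    # initial translation only (general affine init not decomposed)
    p[1:3] <- init$matrix[1:3, 4]
  } else {
    # centre-of-mass initialisation
    p[1:3] <- com_world(moving) - com_world(fixed)
  }
  trace_costs <- c()
  for (fw in fwhm_levels) {
    mv <- smooth_image(moving, fw)
    fx <- smooth_image(fixed, fw)
    idx <- stride_index(fx$grid, if (fw > 0) stride else 1L)
    pts_fix <- grid_world_coords(fx$grid)[idx, , drop = FALSE]
    vals_fix <- as.numeric(fx$values)[idx]
    costf <- function(par) {
      A <- affine_from_params(par, dof, centre)
      pm <- apply_affine_points(A, pts_fix)
      vox <- world_to_voxel_points(mv$grid, pm)
      pred <- interp_at_voxels(mv$values, vox, order = 1, oob = "zero")$values
      mean((pred - vals_fix)^2)
    }
    # scale parameters so Nelder-Mead steps are comparable across types
    parscale <- c(rep(2, 3), rep(0.05, 3),
                  if (dof == "affine12") c(rep(0.05, 3), rep(0.05, 3)))
    opt <- optim(p, costf, method = "Nelder-Mead",
                 control = list(maxit = maxit, parscale = parscale,
                                reltol = 1e-8))
    p <- opt$par
    trace_costs <- c(trace_costs, opt$value)
  }
  out <- affine_from_params(p, dof, centre)
  attr(out, "cost") <- trace_costs[length(trace_costs)]
  attr(out, "trace") <- trace_costs
  out
}

com_world <- function(img) {
  w <- pmax(as.numeric(img$values), 0)
  if (sum(w) == 0) return(c(0, 0, 0))
  pts <- grid_world_coords(img$grid)
  colSums(pts * w) / sum(w)
}

stride_index <- function(grid, stride) {
  if (stride <= 1L) return(seq_len(n_voxels(grid)))
  s <- grid$shape
  keep <- function(n) seq(1L, n, by = stride)
  i <- keep(s[1]); j <- keep(s[2]); k <- keep(s[3])
  idx <- as.vector(outer(outer(i, (j - 1L) * s[1], `+`),
                         (k - 1L) * s[1] * s[2], `+`))
  sort(idx)
}

# --- weight masks ----------------------------------------------------------

#' Intracranial weight mask from a soft brain mask
#'
#' Thresholds the soft mask at 0.1 and binarises, multiplies by 7 and adds 1
#' (so intra/extracranial weights are 8 and 1, ratio 8:1), then rescales so
#' the whole-volume mean is exactly 1.
#'
#' @param soft_brain_mask `WeightImage` or `ScalarImage` with values in `[0, 1]`.
#' @return `WeightImage` flagged mean-normalised.
#' @export
make_weight_mask <- function(soft_brain_mask) {
  v <- soft_brain_mask$values
  stopifnot(min(v) >= 0, max(v) <= 1 + 1e-9)
  inside <- v > 0.1
  if (!any(inside)) stop("empty mask after thresholding at 0.1")
  w <- as.numeric(inside) * 7 + 1
  w <- w / mean(w)
  out <- weight_image(soft_brain_mask$grid, w)
  attr(out, "mean_normalised") <- TRUE
  out
}

#' Reduced DTI mask from a binary brain mask
#'
#' 3x3x3 box-mean smoothing (zero padded), thresholding at 0.9 and one-voxel
#' morphological erosion (6-connectivity). With `normalised = FALSE` the box
#' filter is an unnormalised sum (then thresholded at 0.9 * 27).
#'
#' @param binary_mask `ScalarImage` with 0/1 values.
#' @param normalised divide the box filter by 27 (default) so the threshold
#'   acts on a `[0, 1]` scale.
#' @return `WeightImage` (binary 0/1 values).
#' @export
make_dti_soft_mask <- function(binary_mask, normalised = TRUE) {
  v <- binary_mask$values
  sm <- box_mean3(v)
  # literal reading: unnormalised box sum thresholded at 0.9 (dilation-like);
  # default reading: box mean so the 0.9 threshold acts on a [0, 1] scale
  b <- if (normalised) sm >= 0.9 - 1e-12 else (sm * 27) >= 0.9 - 1e-9
  er <- erode6(b)
  weight_image(binary_mask$grid, as.numeric(er))
}

box_mean3 <- function(v) {
  k <- rep(1 / 3, 3)
  for (axis in 1:3) v <- conv_axis(v, k, axis)
  v
}

erode6 <- function(b) {
  s <- dim(b)
  out <- b
  shift1 <- function(a, axis, by) {
    r <- array(FALSE, dim = s)
    n <- s[axis]
    src <- seq_len(n) - by
    ok <- src >= 1L & src <= n
    tgt <- which(ok)
    switch(axis,
           { r[tgt, , ] <- a[src[ok], , ] },
           { r[, tgt, ] <- a[, src[ok], ] },
           { r[, , tgt] <- a[, , src[ok]] })
    r
  }
  for (axis in 1:3) for (by in c(-1L, 1L)) out <- out & shift1(b, axis, by)
  out
}

#' Smoothly clamp high extracranial intensities
#'
#' Outside-brain intensities above the given percentile of the outside-brain
#' distribution are compressed with an exponential-saturation map
#' `v -> thr + S (1 - exp(-(v - thr)/S))`, `S = softness * (max - thr)`:
#' continuous, differentiable at the threshold (unit slope) and strictly
#' monotone, so the intensity ordering is preserved. In-brain voxels are
#' untouched. Output never exceeds `thr + softness * (max - thr)`.
#'
#' @param t1 `ScalarImage`.
#' @param brain_mask binary `ScalarImage` (1 = in brain).
#' @param percentile percentile in (50, 100) defining the clamp threshold.
#' @param softness fraction of the above-threshold range retained.
#' @return clamped `ScalarImage`.
#' @export
clamp_scalp_intensities <- function(t1, brain_mask, percentile = 99,
                                    softness = 0.2) {
  stopifnot(percentile > 50, percentile < 100)
  outside <- brain_mask$values < 0.5
  v <- t1$values
  ov <- v[outside]
  if (!length(ov)) return(t1)
  thr <- quantile(ov, percentile / 100, names = FALSE)
  vmax <- max(ov)
  if (vmax <= thr) return(t1)
  S <- softness * (vmax - thr)
  hi <- outside & v > thr
  v[hi] <- thr + S * (1 - exp(-(v[hi] - thr) / S))
  scalar_image(t1$grid, v)
}

# --- affine template -------------------------------------------------------

#' Build the unbiased affine template
#'
#' Pairwise affine (12-DOF) registration of every subject's T1 channel to a
#' seed subject, matrix-log midspace unbiasing, optional rigid (6-DOF)
#' alignment of the median template to a reference image, and concatenation
#' into one final transform per subject. Scalar channels are combined by
#' voxel-wise median (sharper than the mean at this early stage), tensors by
#' the log-Euclidean valid-voxel mean, and binary masks are resampled with
#' trilinear interpolation and averaged into soft masks.
#'
#' @param cohort `SyntheticCohort` (or any list with `$subjects`).
#' @param seed_subject index of the registration reference subject.
#' @param reference optional `ScalarImage`; when given, the median template
#'   is rigidly aligned to it.
#' @param maxit,fwhm_levels passed to [affine_register()].
#' @param verbose print progress.
#' @return list with `template` (`MultimodalTemplate`) and `affines` (list of
#'   per-subject `AffineTransform`s, template space -> subject space).
#' @export
build_affine_template <- function(cohort, seed_subject = 1L, reference = NULL,
                                  maxit = 250, fwhm_levels = c(12, 6),
                                  verbose = FALSE) {
  subs <- cohort$subjects
  n <- length(subs)
  stopifnot(n >= 1L)
  seed_img <- subs[[seed_subject]]$t1
  affs <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == seed_subject) { affs[[i]] <- affine_identity("rigid6"); next }
    a <- tryCatch(
      affine_register(subs[[i]]$t1, seed_img, dof = "affine12",
                      fwhm_levels = fwhm_levels, maxit = maxit),
      error = function(e) stop(sprintf("affine registration failed for subject %s: %s",
                                       subs[[i]]$id, conditionMessage(e))))
    affs[[i]] <- a
    if (verbose) message("registered ", subs[[i]]$id)
  }
  mid <- if (n >= 2) midspace_transforms(affs) else affs
  grid <- seed_img$grid
  final <- mid
  if (!is.null(reference)) {
    tmp_med <- median_resample(subs, mid, grid, "t1")
    r <- affine_register(tmp_med, reference, dof = "rigid6",
                         fwhm_levels = fwhm_levels, maxit = maxit)
    # reference-space point x -> midspace (r) -> subject (mid_n)
    final <- lapply(mid, function(m) affine_compose(m, r))
    grid <- reference$grid
  }
  template <- average_affine_channels(subs, final, grid)
  list(template = template, affines = final)
}

median_resample <- function(subs, affs, grid, channel) {
  imgs <- lapply(seq_along(subs), function(i)
    resample_scalar(subs[[i]][[channel]], affs[[i]], order = 3, out_grid = grid))
  voxelwise_median(imgs)
}

average_affine_channels <- function(subs, affs, grid) {
  t1 <- median_resample(subs, affs, grid, "t1")
  flair <- median_resample(subs, affs, grid, "flair")
  dtis <- lapply(seq_along(subs), function(i)
    resample_tensor(subs[[i]]$dti, affs[[i]], out_grid = grid))
  dti <- tensor_mean_valid(dtis)
  masks <- lapply(seq_along(subs), function(i)
    resample_scalar(subs[[i]]$brain_mask, affs[[i]], order = 1, out_grid = grid))
  soft_t1 <- Reduce(`+`, lapply(masks, `[[`, "values")) / length(masks)
  dmasks <- lapply(seq_along(subs), function(i) {
    dm <- make_dti_soft_mask(subs[[i]]$brain_mask)
    resample_scalar(dm, affs[[i]], order = 1, out_grid = grid)
  })
  soft_dti <- Reduce(`+`, lapply(dmasks, `[[`, "values")) / length(dmasks)
  multimodal_template(
    t1 = t1, flair = flair, dti = dti,
    soft_t1_mask = weight_image(grid, pmin(pmax(soft_t1, 0), 1)),
    soft_dti_mask = weight_image(grid, pmin(pmax(soft_dti, 0), 1)),
    iteration = 0L)
}
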