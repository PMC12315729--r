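#' Symmetric 3x3 tensor volume
#'
#' Tensors are stored as 6 unique components in lower-triangle row order
#' `(Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)`. A voxel is valid only when its tensor is
#' nonzero with a strictly positive largest eigenvalue; validity is recomputed
#' on construction unless supplied.
#'
#' @param grid `ImageGrid`.
#' @param tensors numeric array `c(grid$shape, 6)` (or `n_voxels x 6` matrix).
#' @param valid optional logical array `grid$shape`.
#' @return `TensorImage` object.
#' @export
tensor_image <- function(grid, tensors, valid = NULL) {
  stopifnot(inherits(grid, "ImageGrid"))
  tensors <- array(as.numeric(tensors), dim = c(grid$shape, 6L))
  if (!all(is.finite(tensors))) stop("tensor components must be finite")
  tm <- matrix(tensors, ncol = 6L)
  auto_valid <- tensor_rows_valid(tm)
  if (is.null(valid)) valid <- auto_valid else valid <- as.logical(valid) & auto_valid
  structure(list(grid = grid, tensors = tensors,
                 valid = array(valid, dim = grid$shape)),
            class = "TensorImage")
}

# a row is usable if nonzero and its largest eigenvalue is positive
tensor_rows_valid <- function(tm) {
  nz <- rowSums(abs(tm)) > 0
  out <- rep(FALSE, nrow(tm))
  if (any(nz)) {
    ev <- eig_sym3_batch(tm[nz, , drop = FALSE])$values
    out[nz] <- ev[, 1] > 0
  }
  out
}

tensor_matrix <- function(timg) matrix(timg$tensors, ncol = 6L)

#' @export
print.TensorImage <- function(x, ...) {
  cat("TensorImage on ")
  print(x$grid)
  cat("  valid voxels:", sum(x$valid), "/", n_voxels(x$grid), "\n")
  invisible(x)
}

#' Pack a symmetric 3x3 matrix to 6 components (and back)
#' @param D symmetric 3x3 matrix.
#' @export
tensor6_from_matrix <- function(D) c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])

#' @rdname tensor6_from_matrix
#' @param t6 length-6 component vector `(xx, xy, xz, yy, yz, zz)`.
#' @export
matrix_from_tensor6 <- function(t6) {
  matrix(c(t6[1], t6[2], t6[3],
           t6[2], t6[4], t6[5],
           t6[3], t6[5], t6[6]), 3, 3)
}

#' Log-Euclidean mean of tensors
#'
#' Matrix exponential of the Euclidean mean of matrix logarithms, taken over
#' valid tensors only. Eigenvalues below `clamp_frac` times the largest are
#' clamped before the log; tensors whose largest eigenvalue is non-positive
#' are invalid. With no valid input the zero tensor is returned with
#' attribute `"valid" = FALSE`. Log-domain averaging preserves anisotropy and
#' avoids the eigenvalue swelling of the Euclidean mean.
#'
#' @param tensors list of symmetric 3x3 matrices, or an `n x 6` component matrix.
#' @param valid optional logical vector marking usable entries.
#' @param clamp_frac relative eigenvalue floor for the matrix log.
#' @return symmetric 3x3 matrix (attribute `"valid"`).
#' @export
log_euclidean_mean <- function(tensors, valid = NULL, clamp_frac = 1e-9) {
  tm <- if (is.matrix(tensors) && ncol(tensors) == 6) tensors else
    t(vapply(tensors, tensor6_from_matrix, numeric(6)))
  if (is.null(valid)) valid <- rep(TRUE, nrow(tm))
  lg <- logm_sym3_batch(tm, clamp_frac)
  use <- valid & lg$valid
  if (!any(use)) {
    out <- matrix(0, 3, 3)
    attr(out, "valid") <- FALSE
    return(out)
  }
  mlog <- colMeans(lg$log[use, , drop = FALSE])
  out <- matrix_from_tensor6(as.numeric(expm_sym3_batch(matrix(mlog, 1, 6))))
  attr(out, "valid") <- TRUE
  out
}

#' Fractional anisotropy map
#'
#' Standard FA from tensor eigenvalues, 0 where the voxel is invalid.
#' @param timg `TensorImage`.
#' @return `ScalarImage` with values in `[0, 1]`.
#' @export
fa_map <- function(timg) {
  stopifnot(inherits(timg, "TensorImage"))
  tm <- tensor_matrix(timg)
  fa <- numeric(nrow(tm))
  idx <- which(as.logical(timg$valid))
  if (length(idx)) {
    ev <- eig_sym3_batch(tm[idx, , drop = FALSE])$values
    fa[idx] <- fa_from_eigenvalues(ev)
  }
  scalar_image(timg$grid, fa)
}

fa_from_eigenvalues <- function(ev) {
  l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
  num <- (l1 - l2)^2 + (l2 - l3)^2 + (l3 - l1)^2
  den <- 2 * (l1^2 + l2^2 + l3^2)
  out <- ifelse(den > 0, sqrt(pmin(num / den, 1)), 0)
  out
}

#' FA of a single tensor
#' @param D symmetric 3x3 matrix.
#' @export
tensor_fa <- function(D) {
  ev <- eig_sym3_batch(matrix(tensor6_from_matrix(D), 1, 6))$values
  fa_from_eigenvalues(ev)[1]
}

#' Resample a tensor image through a map with PPD reorientation
#'
#' Components are interpolated in the log-tensor domain (trilinear; the log
#' prevents swelling and keeps interpolants positive definite), then each
#' tensor is reoriented with the preservation-of-principal-directions rule
#' using the local Jacobian of the map: for pullback map `phi` the anatomical
#' transformation of directions is `J(phi)^{-1}`, so the principal frame is
#' carried by `M = J^{-1}` (normalised within PPD). Output voxels are invalid
#' where any contributing source voxel is invalid, the sample point maps
#' outside the source grid, or the local Jacobian is singular.
#'
#' @param timg source `TensorImage`.
#' @param map `DisplacementField` (output on its grid) or `AffineTransform`.
#' @param out_grid output grid when `map` is affine (default: source grid).
#' @return resampled `TensorImage`.
#' @export
resample_tensor <- function(timg, map, out_grid = NULL) {
  stopifnot(inherits(timg, "TensorImage"))
  src_grid <- timg$grid
  if (inherits(map, "DisplacementField")) {
    grid <- map$grid
    pts <- mapped_world_points(map)
    Jrows <- warp_jacobian_matrices(map)
  } else if (inherits(map, "AffineTransform")) {
    grid <- if (is.null(out_grid)) src_grid else out_grid
    pts <- apply_affine_points(map, grid_world_coords(grid))
    Jrows <- matrix(rep(as.numeric(map$matrix[1:3, 1:3]), each = n_voxels(grid)),
                    n_voxels(grid), 9)
  } else stop("map must be a DisplacementField or AffineTransform")

  # log-tensor field over valid source voxels
  tm <- tensor_matrix(timg)
  lg <- logm_sym3_batch(tm, 1e-9)
  src_valid <- as.logical(timg$valid) & lg$valid
  logt <- lg$log
  logt[!src_valid, ] <- 0

  vox <- world_to_voxel_points(src_grid, pts)
  N <- nrow(vox)
  out_log <- matrix(0, N, 6)
  oob <- rep(FALSE, N)
  for (k in 1:6) {
    res <- interp_at_voxels(array(logt[, k], src_grid$shape), vox, order = 1, oob = "zero")
    out_log[, k] <- res$values
    oob <- oob | res$oob
  }
  # validity: all 8 trilinear contributors must be valid
  vres <- interp_at_voxels(array(as.numeric(src_valid), src_grid$shape), vox,
                           order = 1, oob = "zero")
  valid <- !oob & vres$values > 1 - 1e-9

  out6 <- matrix(0, N, 6)
  idx <- which(valid)
  if (length(idx)) {
    tens <- expm_sym3_batch(out_log[idx, , drop = FALSE])
    # anatomical direction transport: inverse of the pullback map's Jacobian
    Minv <- invert3_rows(Jrows[idx, , drop = FALSE])
    keep <- Minv$ok
    pp <- ppd_reorient_batch(tens[keep, , drop = FALSE],
                             Minv$inv[keep, , drop = FALSE])
    sub <- idx[keep]
    out6[sub[pp$valid], ] <- pp$tensors[pp$valid, , drop = FALSE]
    valid[idx[!keep]] <- FALSE
    valid[sub[!pp$valid]] <- FALSE
  }
  tensor_image(grid, out6, valid = array(valid, grid$shape))
}

# batch inverse of 3x3 matrices stored row-wise column-major
invert3_rows <- function(J) {
  det <- det3_rows(J)
  ok <- abs(det) > 1e-12
  a <- J[, 1]; d <- J[, 2]; g <- J[, 3]
  b <- J[, 4]; e <- J[, 5]; h <- J[, 6]
  c <- J[, 7]; f <- J[, 8]; i <- J[, 9]
  inv <- cbind(e * i - f * h, f * g - d * i, d * h - e * g,
               c * h - b * i, a * i - c * g, b * g - a * h,
               b * f - c * e, c * d - a * f, a * e - b * d) / ifelse(ok, det, 1)
  list(inv = inv, ok = ok)
}

#' Log-Euclidean voxel-wise average of tensor images
#'
#' At each voxel the mean is taken only across inputs valid there; voxels
#' with no valid contributor are zero and invalid.
#' @param timgs nonempty list of `TensorImage`s on one grid.
#' @export
tensor_mean_valid <- function(timgs) {
  if (length(timgs) == 0L) stop("tensor_mean_valid: empty list")
  g <- timgs[[1]]$grid
  N <- n_voxels(g)
  acc <- matrix(0, N, 6); cnt <- numeric(N)
  for (ti in timgs) {
    stop_if_grid_mismatch(g, ti$grid, "tensor images")
    lg <- logm_sym3_batch(tensor_matrix(ti), 1e-9)
    use <- as.logical(ti$valid) & lg$valid
    acc[use, ] <- acc[use, , drop = FALSE] + lg$log[use, , drop = FALSE]
    cnt <- cnt + use
  }
  any_valid <- cnt > 0
  out <- matrix(0, N, 6)
  if (any(any_valid)) {
    ml <- acc[any_valid, , drop = FALSE] / cnt[any_valid]
    out[any_valid, ] <- expm_sym3_batch(ml)
  }
  tensor_image(g, out, valid = array(any_valid, g$shape))
}
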