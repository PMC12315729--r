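#' Dense displacement field
#'
#' Represents the map `phi(x) = x + d(x)` for world point `x` on the grid,
#' with `d` in world mm. Fields are pullback resampling maps from template
#' space to subject space.
#'
#' @param grid `ImageGrid` the field lives on.
#' @param disp numeric array `c(grid$shape, 3)` of mm displacements, or an
#'   `n_voxels x 3` matrix.
#' @return `DisplacementField` object.
#' @export
displacement_field <- function(grid, disp) {
  stopifnot(inherits(grid, "ImageGrid"))
  disp <- array(as.numeric(disp), dim = c(grid$shape, 3L))
  if (!all(is.finite(disp))) stop("displacements must be finite")
  structure(list(grid = grid, disp = disp), class = "DisplacementField")
}

#' Zero (identity) displacement field
#' @param grid `ImageGrid`.
#' @export
zero_field <- function(grid) {
  displacement_field(grid, array(0, dim = c(grid$shape, 3L)))
}

#' @export
print.DisplacementField <- function(x, ...) {
  mag <- sqrt(rowSums(field_disp_matrix(x)^2))
  cat("DisplacementField on ")
  print(x$grid)
  cat("  |d| max:", signif(max(mag), 4), "mm, mean:", signif(mean(mag), 4), "mm\n")
  invisible(x)
}

# Interpolate a field's displacement vectors at world points (trilinear,
# boundary-clamped). Returns list(disp = N x 3, oob = logical N).
eval_field_disp <- function(field, pts_world) {
  vox <- world_to_voxel_points(field$grid, pts_world)
  s <- field$grid$shape
  d <- interp3_multi_cpp(matrix(field$disp, ncol = 3), as.integer(s), vox, 1L)
  oob <- vox[, 1] < 0 | vox[, 2] < 0 | vox[, 3] < 0 |
    vox[, 1] > s[1] - 1 | vox[, 2] > s[2] - 1 | vox[, 3] > s[3] - 1
  list(disp = d, oob = oob)
}

#' Compose two displacement fields
#'
#' Returns `h` with `h(x) = outer(inner(x))`: the outer map is evaluated (by
#' trilinear, boundary-clamped interpolation of its displacement) at the
#' points the inner map sends each grid voxel to. The composition convention
#' is mathematical: `(f o g)(x) = f(g(x))`.
#'
#' @param outer,inner `DisplacementField`s; the output lives on `inner`'s grid.
#' @return `DisplacementField` with attribute `"oob_count"`: number of grid
#'   points whose inner-mapped location fell outside `outer`'s grid (their
#'   outer displacement was boundary-clamped).
#' @export
compose_warps <- function(outer, inner) {
  stopifnot(inherits(outer, "DisplacementField"), inherits(inner, "DisplacementField"))
  y <- mapped_world_points(inner)
  ev <- eval_field_disp(outer, y)
  h <- displacement_field(inner$grid, field_disp_matrix(inner) + ev$disp)
  attr(h, "oob_count") <- sum(ev$oob)
  h
}

#' Compose an affine with a displacement field
#'
#' Returns `h(x) = affine(warp(x))` represented exactly as a displacement
#' field on `warp`'s grid; the affine part involves no interpolation.
#'
#' @param affine `AffineTransform` applied after the warp.
#' @param warp `DisplacementField`.
#' @export
compose_affine_warp <- function(affine, warp) {
  stopifnot(inherits(affine, "AffineTransform"), inherits(warp, "DisplacementField"))
  x <- grid_world_coords(warp$grid)
  y <- apply_affine_points(affine, x + field_disp_matrix(warp))
  displacement_field(warp$grid, y - x)
}

#' Represent an affine as a displacement field on a grid
#' @param affine `AffineTransform`.
#' @param grid target `ImageGrid`.
#' @export
affine_to_field <- function(affine, grid) {
  x <- grid_world_coords(grid)
  displacement_field(grid, apply_affine_points(affine, x) - x)
}

#' Invert a displacement field
#'
#' Fixed-point iteration `d_inv(x) <- -d(x + d_inv(x))` starting from
#' `d_inv = -d`. Converges for displacements smooth relative to the grid
#' spacing.
#'
#' @param warp `DisplacementField`.
#' @param tol convergence tolerance in mm on the residual
#'   `max |d_inv_new - d_inv_old|`.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   maximum residual.
#' @return inverse `DisplacementField`.
#' @export
invert_warp <- function(warp, tol = 0.01, max_iter = 50L) {
  x <- grid_world_coords(warp$grid)
  dinv <- -field_disp_matrix(warp)
  res <- Inf
  for (it in seq_len(max_iter)) {
    dnew <- -eval_field_disp(warp, x + dinv)$disp
    res <- max(abs(dnew - dinv))
    dinv <- dnew
    if (res <= tol) break
  }
  if (res > tol)
    stop(sprintf("warp inversion did not converge: residual %.4g mm after %d iterations",
                 res, max_iter))
  displacement_field(warp$grid, dinv)
}

#' Voxel-wise mean of displacement fields
#'
#' Euclidean (small-deformation) average of the displacement vectors.
#' @param warps nonempty list of `DisplacementField`s on one common grid.
#' @export
mean_warp <- function(warps) {
  if (length(warps) == 0L) stop("mean_warp: empty list")
  g <- warps[[1]]$grid
  acc <- array(0, dim = c(g$shape, 3L))
  for (w in warps) {
    stop_if_grid_mismatch(g, w$grid, "warps in mean_warp")
    acc <- acc + w$disp
  }
  displacement_field(g, acc / length(warps))
}

#' Scale a displacement field
#' @param warp `DisplacementField`.
#' @param s scalar factor.
#' @export
scale_warp <- function(warp, s) displacement_field(warp$grid, warp$disp * s)

# Spatial 3x3 Jacobian of phi(x) = x + d(x) at every voxel, world units.
# Central differences in the interior, one-sided at the boundary.
# Returns an N x 9 matrix (column-major 3x3 per row).
warp_jacobian_matrices <- function(warp) {
  g <- warp$grid
  s <- g$shape
  if (any(s < 2L)) stop("jacobian needs >= 2 voxels per axis")
  Ainv <- solve(g$voxel_to_world)[1:3, 1:3]
  N <- n_voxels(g)
  # dd[k, l]: derivative of displacement component k wrt voxel index l
  dd <- vector("list", 9)
  for (k in 1:3) {
    v <- warp$disp[, , , k]
    for (l in 1:3) dd[[(l - 1) * 3 + k]] <- array_diff(v, l)
  }
  J <- matrix(0, N, 9)
  # world-gradient G = (dd/dindex) %*% Ainv ; J = I + G
  for (r in 1:3) for (c in 1:3) {
    acc <- 0
    for (l in 1:3) acc <- acc + dd[[(l - 1) * 3 + r]] * Ainv[l, c]
    J[, (c - 1) * 3 + r] <- as.numeric(acc) + as.numeric(r == c)
  }
  J
}

# finite difference of a 3-D array along axis, central interior / one-sided ends
array_diff <- function(v, axis) {
  s <- dim(v)
  n <- s[axis]
  if (n == 1L) return(array(0, dim = s))
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  h <- idx_p - idx_m
  slicer <- function(idx) {
    switch(axis, v[idx, , , drop = FALSE], v[, idx, , drop = FALSE], v[, , idx, drop = FALSE])
  }
  d <- slicer(idx_p) - slicer(idx_m)
  hh <- switch(axis,
               array(h, dim = s),
               aperm(array(h, dim = s[c(2, 1, 3)]), c(2, 1, 3)),
               aperm(array(h, dim = s[c(3, 1, 2)]), c(2, 3, 1)))
  d / hh
}

det3_rows <- function(J) {
  a <- J[, 1]; b <- J[, 4]; c <- J[, 7]
  d <- J[, 2]; e <- J[, 5]; f <- J[, 8]
  g <- J[, 3]; h <- J[, 6]; i <- J[, 9]
  a * (e * i - f * h) - b * (d * i - f * g) + c * (d * h - e * g)
}

#' Jacobian determinant map of a warp
#'
#' Voxel-wise determinant of the spatial gradient of `phi(x) = x + d(x)`
#' (central differences interior, one-sided at the boundary), in world units.
#' Values > 1 indicate local expansion of template space into subject space.
#'
#' @param warp `DisplacementField`.
#' @return `ScalarImage` of determinants.
#' @export
jacobian_determinant_map <- function(warp) {
  scalar_image(warp$grid, det3_rows(warp_jacobian_matrices(warp)))
}

#' Log-Jacobian map
#'
#' Natural log of [jacobian_determinant_map()]. Non-positive determinants are
#' masked to 0 and counted in attribute `"n_nonpositive"`.
#' @param warp `DisplacementField`.
#' @export
log_jacobian_map <- function(warp) {
  j <- jacobian_determinant_map(warp)
  bad <- j$values <= 0
  v <- j$values
  v[bad] <- 1
  out <- scalar_image(warp$grid, log(v))
  attr(out, "n_nonpositive") <- sum(bad)
  out
}

#' Voxel-wise median over scalar images
#' @param images nonempty list of `ScalarImage`s on a common grid.
#' @export
voxelwise_median <- function(images) {
  if (length(images) == 0L) stop("voxelwise_median: empty list")
  g <- images[[1]]$grid
  for (im in images) stop_if_grid_mismatch(g, im$grid, "images")
  m <- vapply(images, function(im) as.numeric(im$values), numeric(n_voxels(g)))
  scalar_image(g, row_medians(m))
}

row_medians <- function(m) {
  n <- ncol(m)
  if (n == 1L) return(m[, 1])
  sm <- matrix(apply(m, 1L, sort.int, method = "quick"), nrow = n)
  if (n %% 2L == 1L) sm[(n + 1L) %/% 2L, ] else
    (sm[n %/% 2L, ] + sm[n %/% 2L + 1L, ]) / 2
}

#' Voxel-wise mean over valid voxels
#'
#' Averages only values whose validity flag is `TRUE`; voxels with no valid
#' contributor are 0.
#' @param images nonempty list of `ScalarImage`s.
#' @param valid_masks list of logical arrays (or 0/1 `ScalarImage`s), one per image.
#' @export
voxelwise_mean_valid <- function(images, valid_masks) {
  if (length(images) == 0L) stop("voxelwise_mean_valid: empty list")
  stopifnot(length(images) == length(valid_masks))
  g <- images[[1]]$grid
  acc <- array(0, g$shape); cnt <- array(0, g$shape)
  for (i in seq_along(images)) {
    stop_if_grid_mismatch(g, images[[i]]$grid, "images")
    vm <- valid_masks[[i]]
    if (inherits(vm, "ScalarImage")) vm <- vm$values > 0.5
    acc <- acc + images[[i]]$values * vm
    cnt <- cnt + vm
  }
  scalar_image(g, ifelse(cnt > 0, acc / pmax(cnt, 1), 0))
}
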