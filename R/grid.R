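#' Sampling grid of a volume
#'
#' An `ImageGrid` couples an integer voxel lattice with a 4x4 voxel-to-world
#' affine (mm). Voxel indices are 0-based throughout the package; the world
#' position of voxel `(i, j, k)` is `voxel_to_world %*% c(i, j, k, 1)`.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param voxel_to_world 4x4 matrix mapping 0-based voxel indices to world mm.
#'   Defaults to an isotropic grid centred on the world origin.
#' @param voxel_size voxel edge length in mm used when `voxel_to_world` is
#'   not supplied.
#' @return An object of class `ImageGrid`.
#' @export
image_grid <- function(shape, voxel_to_world = NULL, voxel_size = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (is.null(voxel_to_world)) {
    voxel_to_world <- diag(c(rep(voxel_size, 3), 1))
    voxel_to_world[1:3, 4] <- -voxel_size * (shape - 1) / 2
  }
  voxel_to_world <- as.matrix(voxel_to_world)
  stopifnot(all(dim(voxel_to_world) == c(4L, 4L)))
  if (abs(det(voxel_to_world)) < .Machine$double.eps)
    stop("voxel_to_world must be invertible")
  vs <- sqrt(colSums(voxel_to_world[1:3, 1:3]^2))
  if (any(vs <= 0)) stop("voxel sizes must be strictly positive")
  structure(list(shape = shape, voxel_to_world = voxel_to_world),
            class = "ImageGrid")
}

#' @export
print.ImageGrid <- function(x, ...) {
  cat("ImageGrid", paste(x$shape, collapse = " x "),
      "voxels, voxel size", paste(signif(grid_voxel_size(x), 4), collapse = " x "),
      "mm\n")
  invisible(x)
}

#' Voxel edge lengths of a grid in mm
#' @param grid an `ImageGrid`.
#' @return numeric length-3 vector.
#' @export
grid_voxel_size <- function(grid) {
  sqrt(colSums(grid$voxel_to_world[1:3, 1:3]^2))
}

grid_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_to_world - b$voxel_to_world)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!grid_equal(a, b)) stop(sprintf("grid mismatch between %s", what))
}

n_voxels <- function(grid) prod(grid$shape)

# N x 3 matrix of 0-based voxel indices for all voxels, column-major order
# (first axis fastest), matching R array storage.
grid_voxel_coords <- function(grid) {
  s <- grid$shape
  cbind(
    rep_len(0:(s[1] - 1L), prod(s)),
    rep_len(rep(0:(s[2] - 1L), each = s[1]), prod(s)),
    rep(0:(s[3] - 1L), each = s[1] * s[2])
  )
}

# N x 3 world coordinates (mm) of all grid voxels.
grid_world_coords <- function(grid) {
  voxel_to_world_points(grid, grid_voxel_coords(grid))
}

voxel_to_world_points <- function(grid, vox) {
  A <- grid$voxel_to_world
  sweep(vox %*% t(A[1:3, 1:3]), 2, A[1:3, 4], `+`)
}

world_to_voxel_points <- function(grid, pts) {
  A <- solve(grid$voxel_to_world)
  sweep(pts %*% t(A[1:3, 1:3]), 2, A[1:3, 4], `+`)
}

#' Scalar-valued volume
#'
#' @param grid an `ImageGrid`.
#' @param values numeric array with `dim == grid$shape` (a vector of matching
#'   length is reshaped).
#' @return `ScalarImage` object.
#' @export
scalar_image <- function(grid, values) {
  stopifnot(inherits(grid, "ImageGrid"))
  values <- array(as.numeric(values), dim = grid$shape)
  if (!all(is.finite(values))) stop("ScalarImage values must be finite")
  structure(list(grid = grid, values = values), class = "ScalarImage")
}

#' @export
print.ScalarImage <- function(x, ...) {
  cat("ScalarImage on ")
  print(x$grid)
  cat("  range:", paste(signif(range(x$values), 5), collapse = " .. "), "\n")
  invisible(x)
}

#' Nonnegative voxel-wise weights (soft masks)
#'
#' @param grid an `ImageGrid`.
#' @param weights nonnegative numeric array.
#' @return `WeightImage` object.
#' @export
weight_image <- function(grid, weights) {
  img <- scalar_image(grid, weights)
  if (any(img$values < 0)) stop("weights must be nonnegative")
  class(img) <- c("WeightImage", "ScalarImage")
  img
}

#' World-to-world affine transform
#'
#' @param matrix 4x4 invertible matrix acting on world mm coordinates.
#' @param dof_tag `"rigid6"` or `"affine12"`. Rigid transforms must have an
#'   orthogonal, determinant +1 linear part (tolerance 1e-6).
#' @return `AffineTransform` object.
#' @export
affine_transform <- function(matrix, dof_tag = c("affine12", "rigid6")) {
  dof_tag <- match.arg(dof_tag)
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(4L, 4L)))
  if (abs(det(matrix)) < .Machine$double.eps) stop("affine matrix not invertible")
  if (dof_tag == "rigid6") {
    L <- matrix[1:3, 1:3]
    if (max(abs(t(L) %*% L - diag(3))) > 1e-6 || det(L) < 0)
      stop("rigid6 transform must have an orthogonal, det +1 linear part")
  }
  structure(list(matrix = matrix, dof_tag = dof_tag), class = "AffineTransform")
}

#' Identity affine transform
#' @param dof_tag degrees-of-freedom tag, see [affine_transform()].
#' @export
affine_identity <- function(dof_tag = "rigid6") affine_transform(diag(4), dof_tag)

apply_affine_points <- function(affine, pts) {
  M <- affine$matrix
  sweep(pts %*% t(M[1:3, 1:3]), 2, M[1:3, 4], `+`)
}

#' Invert an affine transform
#' @param affine an `AffineTransform`.
#' @export
affine_inverse <- function(affine) {
  affine_transform(solve(affine$matrix), affine$dof_tag)
}

#' Compose two affine transforms
#'
#' Returns the transform applying `inner` first: `x -> outer(inner(x))`.
#' @param outer,inner `AffineTransform` objects.
#' @export
affine_compose <- function(outer, inner) {
  tag <- if (outer$dof_tag == "rigid6" && inner$dof_tag == "rigid6")
    "rigid6" else "affine12"
  affine_transform(outer$matrix %*% inner$matrix, tag)
}

#' Read / write plain-text 4x4 affine files
#'
#' Whitespace-separated 4-row matrix files (FLIRT-style world-to-world mm).
#' @param path file path.
#' @param dof_tag tag to attach on read.
#' @return `read_affine` returns an `AffineTransform`.
#' @export
read_affine <- function(path, dof_tag = "affine12") {
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  affine_transform(m, dof_tag)
}

#' @rdname read_affine
#' @param affine transform to write.
#' @export
write_affine <- function(affine, path) {
  write.table(format(affine$matrix, digits = 17), path,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
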