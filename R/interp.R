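# Batch interpolation of volumes at continuous 0-based voxel coordinates.
# Thin wrappers around the C++ kernel; all higher-level resampling goes
# through these.

interp_at_voxels <- function(values, pts, order = 1, oob = c("zero", "clamp"),
                             fill = 0) {
  oob <- match.arg(oob)
  if (!order %in% c(0, 1, 3)) stop("interpolation order must be 0, 1 or 3")
  res <- interp3_cpp(as.numeric(values), as.integer(dim(values)), pts,
                     as.integer(order), if (oob == "zero") 0L else 1L, fill)
  res
}

#' Resample a scalar image through a displacement field or affine
#'
#' The map is a pullback: the output value at grid point `x` is the source
#' image interpolated at the mapped world point. Points falling outside the
#' source field of view are set to 0.
#'
#' @param image source `ScalarImage`.
#' @param map a `DisplacementField` (output is on its grid) or an
#'   `AffineTransform` (then `out_grid` gives the output grid, defaulting to
#'   the source grid).
#' @param order interpolation order: 0 (nearest), 1 (trilinear) or
#'   3 (cubic spline, Catmull-Rom). Default 3 for intensities; use 1 for masks.
#' @param out_grid output `ImageGrid` when `map` is affine.
#' @return resampled `ScalarImage`.
#' @export
resample_scalar <- function(image, map, order = 3, out_grid = NULL) {
  stopifnot(inherits(image, "ScalarImage"))
  if (inherits(map, "DisplacementField")) {
    grid <- map$grid
    pts <- mapped_world_points(map)
  } else if (inherits(map, "AffineTransform")) {
    grid <- if (is.null(out_grid)) image$grid else out_grid
    pts <- apply_affine_points(map, grid_world_coords(grid))
  } else stop("map must be a DisplacementField or AffineTransform")
  vox <- world_to_voxel_points(image$grid, pts)
  res <- interp_at_voxels(image$values, vox, order = order, oob = "zero")
  scalar_image(grid, res$values)
}

# world coordinates phi(x) = x + d(x) at every grid voxel of a field
mapped_world_points <- function(field) {
  grid_world_coords(field$grid) + field_disp_matrix(field)
}

field_disp_matrix <- function(field) {
  matrix(field$disp, nrow = n_voxels(field$grid), ncol = 3)
}
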