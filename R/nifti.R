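# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# No NIfTI reader is available in the supported dependency set, so a small
# self-contained implementation of the fixed 348-byte header is provided.
# Only what the package emits is supported on read: float32/float64/int16/
# uint8 data, 3-D scalar volumes, 4-D multi-component volumes, and the
# 5-D (nx, ny, nz, 1, 3) displacement-field convention. The sform (or, if
# absent, a pixdim-derived affine) is the single source of geometry.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L)

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array) and `voxel_to_world` (4x4 sform
#'   affine; voxel indices 0-based).
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1, size = 4)
  endian <- "little"
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- .swap_int(sizeof_hdr)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  readBin(con, "raw", 36)                     # unused header fields
  dim0 <- readBin(con, "integer", 8, size = 2, endian = endian)
  readBin(con, "raw", 14)                     # intent params/codes
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 1, size = 2, endian = endian)  # bitpix
  readBin(con, "integer", 1, size = 2, endian = endian)  # slice_start
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  readBin(con, "raw", 252 - 120)              # slice_end .. aux_file
  qform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  sform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "numeric", 6, size = 4, endian = endian)   # quatern/qoffset
  srow <- matrix(readBin(con, "numeric", 12, size = 4, endian = endian),
                 nrow = 3, byrow = TRUE)
  readBin(con, "raw", 20)                     # intent_name + magic
  nd <- dim0[1]
  dims <- dim0[2:(1 + max(nd, 1))]
  dims <- dims[dims > 0]
  ntot <- prod(dims)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  sz <- switch(as.character(datatype), `2` = 1L, `4` = 2L, `8` = 4L,
               `16` = 4L, `64` = 8L,
               stop("unsupported NIfTI datatype ", datatype))
  what <- if (datatype %in% c(16L, 64L)) "numeric" else "integer"
  signed <- datatype != 2L
  vals <- readBin(con, what, ntot, size = sz, signed = signed, endian = endian)
  vals <- as.numeric(vals)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  aff <- diag(4)
  if (sform_code > 0) {
    aff[1:3, ] <- srow
  } else {
    aff <- diag(c(pixdim[2:4], 1))
  }
  list(data = array(vals, dim = dims), voxel_to_world = aff,
       qform_code = qform_code, sform_code = sform_code)
}

.swap_int <- function(x) {
  sum(bitwShiftL(bitwAnd(bitwShiftR(x, c(0, 8, 16, 24)), 255L), c(24, 16, 8, 0)))
}

#' Write a NIfTI-1 volume
#'
#' @param data numeric array (3-D, 4-D, or 5-D).
#' @param voxel_to_world 4x4 affine written to the sform (and qform code 0).
#' @param path output `.nii` or `.nii.gz` path.
#' @param datatype one of `"float32"`, `"float64"`.
#' @param intent_vector set `TRUE` for displacement fields stored as
#'   `(nx, ny, nz, 1, 3)` with intent code 1007 (vector).
#' @export
write_nifti <- function(data, voxel_to_world, path, datatype = "float32",
                        intent_vector = FALSE) {
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) stop("unsupported datatype ", datatype)
  dims <- dim(data)
  if (is.null(dims)) dims <- length(data)
  nd <- length(dims)
  dim0 <- integer(8); dim0[1] <- nd; dim0[2:(1 + nd)] <- dims
  dim0[dim0 == 0L] <- 1L
  vs <- sqrt(colSums(voxel_to_world[1:3, 1:3]^2))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)
  writeBin(raw(36), con)
  writeBin(as.integer(dim0), con, size = 2)
  writeBin(numeric(3), con, size = 4)                        # intent_p1..p3
  writeBin(as.integer(if (intent_vector) 1007L else 0L), con, size = 2)
  writeBin(as.integer(dt), con, size = 2)                    # datatype
  writeBin(as.integer(8 * c(uint8 = 1, int16 = 2, int32 = 4,
                            float32 = 4, float64 = 8)[[datatype]]), con, size = 2)
  writeBin(0L, con, size = 2)                                # slice_start
  writeBin(as.numeric(c(1, vs, rep(1, 4))), con, size = 4)   # pixdim
  writeBin(352, con, size = 4)                               # vox_offset
  writeBin(c(1, 0), con, size = 4)                           # scl_slope/inter
  writeBin(0L, con, size = 2)                                # slice_end
  writeBin(raw(1), con)                                      # slice_code
  writeBin(as.raw(2L), con)                                  # xyzt_units: mm
  writeBin(numeric(4), con, size = 4)                        # cal_max..toffset
  writeBin(integer(2), con, size = 4)                        # glmax/glmin
  writeBin(charpad("omtemplate", 80), con)
  writeBin(charpad("", 24), con)
  writeBin(0L, con, size = 2)                                # qform_code
  writeBin(1L, con, size = 2)                                # sform_code
  writeBin(numeric(6), con, size = 4)                        # quatern/qoffset
  writeBin(as.numeric(t(voxel_to_world[1:3, ])), con, size = 4)
  writeBin(charpad("", 16), con)                             # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)                 # magic
  writeBin(raw(4), con)                                      # extension flag
  writeBin(as.numeric(data), con,
           size = if (datatype == "float64") 8 else 4)
  invisible(path)
}

charpad <- function(s, n) {
  r <- raw(n)
  b <- charToRaw(s)
  if (length(b)) r[seq_along(b)] <- b
  r
}

#' Scalar image NIfTI round trip
#'
#' @param img `ScalarImage`.
#' @param path output path.
#' @param datatype storage type.
#' @export
write_scalar_nifti <- function(img, path, datatype = "float32") {
  write_nifti(img$values, img$grid$voxel_to_world, path, datatype)
}

#' @rdname write_scalar_nifti
#' @export
read_scalar_nifti <- function(path) {
  nv <- read_nifti(path)
  d <- nv$data
  if (length(dim(d)) > 3) d <- array(d, dim = dim(d)[1:3])
  scalar_image(image_grid(dim(d)[1:3], nv$voxel_to_world), d)
}

#' Displacement field NIfTI round trip
#'
#' Fields are written as 5-D `(nx, ny, nz, 1, 3)` float64 volumes with the
#' NIfTI vector intent, components in world mm.
#' @param field `DisplacementField`.
#' @param path output path.
#' @export
write_field_nifti <- function(field, path) {
  d5 <- array(field$disp, dim = c(field$grid$shape, 1L, 3L))
  write_nifti(d5, field$grid$voxel_to_world, path, "float64", intent_vector = TRUE)
}

#' @rdname write_field_nifti
#' @export
read_field_nifti <- function(path) {
  nv <- read_nifti(path)
  dims <- dim(nv$data)
  shape <- dims[1:3]
  disp <- array(nv$data, dim = c(shape, 3L))
  displacement_field(image_grid(shape, nv$voxel_to_world), disp)
}

#' Tensor image NIfTI round trip
#'
#' 4-D volumes with 6 components in lower-triangle row order
#' `(Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)`.
#' @param timg `TensorImage`.
#' @param path output path.
#' @export
write_tensor_nifti <- function(timg, path) {
  write_nifti(timg$tensors, timg$grid$voxel_to_world, path, "float64")
}

#' @rdname write_tensor_nifti
#' @export
read_tensor_nifti <- function(path) {
  nv <- read_nifti(path)
  dims <- dim(nv$data)
  if (length(dims) == 5L) nv$data <- array(nv$data, dim = dims[c(1:3, 5)])
  tensor_image(image_grid(dims[1:3], nv$voxel_to_world), nv$data)
}
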