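# Validation machinery: Jacobian volumetrics, Dice overlap analysis,
# convergence reporting support.

#' ROI volume from a Jacobian determinant map
#'
#' Sums the Jacobian determinant over the ROI and multiplies by the voxel
#' volume: the volume the ROI occupies after the deformation the map
#' belongs to.
#'
#' @param jac `ScalarImage` of Jacobian determinants.
#' @param roi_mask binary `ScalarImage` on the same grid.
#' @return volume in mm^3.
#' @export
roi_volume_from_jacobian <- function(jac, roi_mask) {
  stop_if_grid_mismatch(jac$grid, roi_mask$grid, "jacobian and ROI")
  inroi <- roi_mask$values > 0.5
  if (!any(inroi)) stop("empty ROI")
  voxvol <- prod(grid_voxel_size(jac$grid))
  sum(jac$values[inroi]) * voxvol
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; `NA` when both masks are empty.
#' @param a,b binary `ScalarImage`s (or logical arrays) on one grid.
#' @export
dice <- function(a, b) {
  av <- if (inherits(a, "ScalarImage")) a$values > 0.5 else as.logical(a)
  bv <- if (inherits(b, "ScalarImage")) b$values > 0.5 else as.logical(b)
  stopifnot(length(av) == length(bv))
  na <- sum(av); nb <- sum(bv)
  if (na + nb == 0L) return(NA_real_)
  2 * sum(av & bv) / (na + nb)
}

#' Pairwise Dice analysis across registration targets
#'
#' For each target and each ROI, computes the Dice coefficient of every
#' unordered subject pair (masks already warped to the target space and
#' binarised at 0.5) and aggregates the mean. Relative differences between
#' two targets follow `(mean_A - mean_B) / mean_B`.
#'
#' @param roi_masks nested list: `roi_masks[[target]][[subject]][[roi]]`,
#'   each a binary `ScalarImage` (or logical array). Missing masks (`NULL`)
#'   skip the pairs involving them.
#' @return `DiceTable`: list with `pairwise` (per target: roi x pair matrix),
#'   `mean_dice` (target x roi), and `relative_difference(a, b)` helper
#'   results for all ordered target pairs.
#' @export
pairwise_dice_analysis <- function(roi_masks) {
  targets <- names(roi_masks)
  stopifnot(length(targets) >= 1L)
  out_pair <- list(); mean_mat <- NULL
  rois <- names(roi_masks[[1]][[1]])
  for (tg in targets) {
    subs <- roi_masks[[tg]]
    n <- length(subs)
    stopifnot(n >= 2L)
    pairs <- utils::combn(n, 2)
    m <- matrix(NA_real_, length(rois), ncol(pairs),
                dimnames = list(rois, NULL))
    for (r in rois) {
      for (pcol in seq_len(ncol(pairs))) {
        i <- pairs[1, pcol]; j <- pairs[2, pcol]
        ma <- subs[[i]][[r]]; mb <- subs[[j]][[r]]
        if (is.null(ma) || is.null(mb)) next
        m[r, pcol] <- dice(ma, mb)
      }
    }
    out_pair[[tg]] <- m
    mean_mat <- rbind(mean_mat, rowMeans(m, na.rm = TRUE))
  }
  rownames(mean_mat) <- targets
  rel <- list()
  if (length(targets) >= 2L) {
    for (a in targets) for (b in setdiff(targets, a)) {
      rel[[paste(a, "vs", b)]] <- setNames(
        as.numeric((mean_mat[a, , drop = FALSE] - mean_mat[b, , drop = FALSE]) /
                     mean_mat[b, , drop = FALSE]), colnames(mean_mat))
    }
  }
  structure(list(pairwise = out_pair, mean_dice = mean_mat,
                 relative_differences = rel),
            class = "DiceTable")
}

#' Relative Dice difference between two targets
#'
#' `(mean pairwise Dice with target a - mean with target b) / mean with b`,
#' per ROI and averaged.
#' @param table `DiceTable` from [pairwise_dice_analysis()].
#' @param a,b target names.
#' @export
dice_relative_difference <- function(table, a, b) {
  ma <- table$mean_dice[a, , drop = FALSE]
  mb <- table$mean_dice[b, , drop = FALSE]
  per_roi <- setNames(as.numeric((ma - mb) / mb), colnames(table$mean_dice))
  list(per_roi = per_roi, mean = mean(per_roi, na.rm = TRUE))
}

#' Warp a binary ROI mask to a target space
#'
#' Trilinear resampling through the map, then binarisation at 0.5.
#' @param mask binary `ScalarImage`.
#' @param map `DisplacementField` or `AffineTransform` (pullback into the
#'   target grid).
#' @param out_grid output grid when `map` is affine.
#' @export
warp_roi_mask <- function(mask, map, out_grid = NULL) {
  r <- resample_scalar(mask, map, order = 1, out_grid = out_grid)
  scalar_image(r$grid, as.numeric(r$values >= 0.5))
}

#' Published cerebral volumes of common adult templates
#'
#' Reference constants (mm^3) for the multimodal Oxford template and the
#' MNI 152 template, and the UKB cohort median/mean, used for scale
#' comparisons: the MNI 152 cerebral volume is about 1.33 times larger than
#' the Oxford multimodal template's, a difference of more than 465 ml.
#' @export
template_volume_stats <- function() {
  list(omm1_mm3 = 1419081, mni152_mm3 = 1884594,
       ukb_median_mm3 = 1433335, ukb_mean_mm3 = 1440417)
}
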