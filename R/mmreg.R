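# Desk-scale multimodal nonlinear registration.
#
# Compatible re-implementation of the cost structure used for template
# construction: weighted sum-of-squared-differences for scalar channels, mean
# squared Frobenius norm for the tensor channel, bending-energy
# regularisation of the displacement, per-channel cost rescaling, and a
# coarse-to-fine schedule over knot-grid spacings and smoothing kernels. The
# displacement is parameterised on a regular knot grid with trilinear basis
# functions and optimised by gradient descent with a backtracking line
# search.

#' Registration parameters
#'
#' @param lambda named channel weights `t1`, `flair`, `dti`, `reg`; the three
#'   data weights default to 1 (all modalities contributing equally).
#' @param schedule data.frame with columns `spacing_mm` (knot spacing,
#'   strictly decreasing), `fwhm_mm` (image smoothing) and `iters`
#'   (optimisation steps per level).
#' @return `RegParams` list.
#' @export
reg_params <- function(lambda = c(t1 = 1, flair = 1, dti = 1, reg = 0.05),
                       schedule = default_reg_schedule()) {
  stopifnot(all(lambda >= 0), sum(lambda[c("t1", "flair", "dti")]) > 0,
            all(diff(schedule$spacing_mm) < 0))
  structure(list(lambda = lambda, schedule = schedule), class = "RegParams")
}

#' Registration schedules
#'
#' The full-scale schedule follows the published one: knot spacing starting
#' at 32 mm and a blurring kernel of 8 mm FWHM, both halved at each of six
#' hierarchical levels (down to 1 mm and 0.25 mm). The desk-scale default
#' truncates to the four coarsest levels, which matches a 48^3 x 3 mm
#' phantom grid.
#'
#' @param levels number of levels retained, starting from the coarsest.
#' @param iters optimisation iterations per level.
#' @export
default_reg_schedule <- function(levels = 4L, iters = 30L) {
  full <- data.frame(spacing_mm = 32 / 2^(0:5), fwhm_mm = 8 / 2^(0:5),
                     iters = iters)
  full[seq_len(levels), , drop = FALSE]
}

# knot grid covering the template domain with one-knot margin
make_knot_grid <- function(grid, spacing_mm) {
  vs <- grid_voxel_size(grid)
  extent <- (grid$shape - 1) * vs
  nk <- pmax(ceiling(extent / spacing_mm) + 3L, 4L)
  A <- grid$voxel_to_world
  # knot 0 sits one spacing before the grid origin along each axis
  k2w <- diag(4)
  k2w[1:3, 1:3] <- A[1:3, 1:3] %*% diag(spacing_mm / vs)
  k2w[1:3, 4] <- A[1:3, 4] - as.numeric(k2w[1:3, 1:3] %*% rep(1, 3))
  image_grid(nk, k2w)
}

# dense displacement from knot coefficients (trilinear basis)
knots_to_field <- function(kgrid, coef, grid) {
  vox <- world_to_voxel_points(kgrid, grid_world_coords(grid))
  d <- matrix(0, n_voxels(grid), 3)
  for (k in 1:3) {
    d[, k] <- interp_at_voxels(array(coef[, k], kgrid$shape), vox,
                               order = 1, oob = "clamp")$values
  }
  displacement_field(grid, d)
}

# aggregate a dense per-voxel gradient (N x 3) onto the knot grid by the
# transpose of the trilinear basis
dense_grad_to_knots <- function(kgrid, grid, gdense) {
  vox <- world_to_voxel_points(kgrid, grid_world_coords(grid))
  scatter_grad_knots_cpp(vox, as.integer(kgrid$shape), gdense)
}

# bending-energy-like regulariser: squared second differences of the knot
# coefficients per axis, scaled by spacing^-4, averaged per knot
bending_energy <- function(kgrid, coef) {
  s <- kgrid$shape
  h <- mean(grid_voxel_size(kgrid))
  e <- 0
  for (k in 1:3) {
    a <- array(coef[, k], s)
    for (axis in 1:3) {
      d2 <- second_diff(a, axis)
      e <- e + sum(d2^2)
    }
  }
  e / (h^4) / prod(s)
}

bending_gradient <- function(kgrid, coef) {
  s <- kgrid$shape
  h <- mean(grid_voxel_size(kgrid))
  G <- matrix(0, prod(s), 3)
  for (k in 1:3) {
    a <- array(coef[, k], s)
    g <- array(0, s)
    for (axis in 1:3) {
      d2 <- second_diff(a, axis)
      g <- g + second_diff_adjoint(d2, axis)
    }
    G[, k] <- 2 * as.numeric(g)
  }
  G / (h^4) / prod(s)
}

second_diff <- function(a, axis) {
  s <- dim(a)
  n <- s[axis]
  out <- array(0, s)
  if (n < 3) return(out)
  idx <- 2:(n - 1)
  sl <- function(i) switch(axis, a[i, , , drop = FALSE],
                           a[, i, , drop = FALSE], a[, , i, drop = FALSE])
  val <- sl(idx + 1L) - 2 * sl(idx) + sl(idx - 1L)
  switch(axis, out[idx, , ] <- val, out[, idx, ] <- val, out[, , idx] <- val)
  out
}

second_diff_adjoint <- function(d2, axis) {
  s <- dim(d2)
  n <- s[axis]
  out <- array(0, s)
  if (n < 3) return(out)
  idx <- 2:(n - 1)
  add <- function(i, v) {
    switch(axis,
           out[i, , ] <<- out[i, , ] + v,
           out[, i, ] <<- out[, i, ] + v,
           out[, , i] <<- out[, , i] + v)
  }
  sl <- function(i) switch(axis, d2[i, , , drop = FALSE],
                           d2[, i, , drop = FALSE], d2[, , i, drop = FALSE])
  v <- sl(idx)
  add(idx + 1L, v); add(idx - 1L, v); add(idx, -2 * v)
  out
}

# --- cost evaluation -------------------------------------------------------

# Evaluate channel costs for a given warp. subject/template: lists with
# t1, flair (ScalarImage) and dti (TensorImage). The full pullback is
# x -> init(x + d(x)). Weights are per-voxel in template space.
#' Per-channel registration costs
#'
#' Weighted mean squared intensity difference for scalar channels, weighted
#' mean squared Frobenius norm of the tensor difference (after finite-strain
#' reorientation of the sampled tensors), and the bending-energy
#' regularisation of the displacement.
#'
#' @param subject,template lists with `t1`, `flair` (`ScalarImage`) and
#'   optionally `dti` (`TensorImage`).
#' @param warp `DisplacementField` on the template grid (nonlinear part).
#' @param weight_masks list with `t1` and `dti` `WeightImage`s (template
#'   space); missing entries mean uniform unit weights.
#' @param init `AffineTransform` composed after the warp.
#' @return named list of costs: `t1`, `flair`, `dti`, `reg` (reg computed on
#'   a knot representation only inside [register_multimodal()]; here 0).
#' @export
channel_costs <- function(subject, template, warp, weight_masks = list(),
                          init = affine_identity()) {
  full <- compose_affine_warp(init, warp)
  wt1 <- weights_or_one(weight_masks$t1, template$t1$grid)
  if (all(wt1 == 0)) stop("all-zero weights")
  out <- list()
  for (ch in c("t1", "flair")) {
    w <- if (ch == "t1") wt1 else weights_or_one(weight_masks[[ch]], template$t1$grid)
    pred <- resample_scalar(subject[[ch]], full, order = 1)
    out[[ch]] <- sum(w * (template[[ch]]$values - pred$values)^2) / sum(w)
  }
  if (!is.null(subject$dti) && !is.null(template$dti)) {
    wd <- weights_or_one(weight_masks$dti, template$t1$grid)
    pred <- resample_tensor(subject$dti, full)
    dt <- tensor_matrix(template$dti) - tensor_matrix(pred)
    fro2 <- frob2_rows(dt)
    use <- as.logical(template$dti$valid) & as.logical(pred$valid)
    wv <- as.numeric(wd) * use
    out$dti <- if (sum(wv) > 0) sum(wv * fro2) / sum(wv) else 0
  }
  out$reg <- 0
  out
}

weights_or_one <- function(w, grid) {
  if (is.null(w)) return(array(1, grid$shape))
  w$values
}

# squared Frobenius norm of symmetric tensors from 6 components per row
frob2_rows <- function(t6) {
  t6[, 1]^2 + t6[, 4]^2 + t6[, 6]^2 + 2 * (t6[, 2]^2 + t6[, 3]^2 + t6[, 5]^2)
}

#' Rescale channel costs to equal effective contributions
#'
#' Returns multiplicative scales making each channel's cost equal to 1 at
#' the supplied iterate, so the channel weights have comparable effects
#' regardless of intensity scaling. A channel whose cost falls below its
#' floor (a small fraction of the channel's squared intensity scale; the
#' channel is essentially matched already) is scaled by the floor instead,
#' so that numerical-noise residuals are not inflated into dominance.
#' Channels with zero cost and no floor keep their previous scale.
#'
#' @param costs named list/vector of nonnegative channel costs.
#' @param prev_scales previous scales (used for zero-cost channels).
#' @param floors optional named vector of per-channel cost floors.
#' @return named numeric vector of scales.
#' @export
rescale_channel_costs <- function(costs, prev_scales = NULL, floors = NULL) {
  ch <- setdiff(names(costs), "reg")
  sc <- setNames(rep(1, length(ch)), ch)
  for (m in ch) {
    cm <- costs[[m]]
    fl <- if (!is.null(floors) && m %in% names(floors)) floors[[m]] else 0
    cm <- max(cm, fl)
    if (is.finite(cm) && cm > 0) sc[m] <- 1 / cm
    else if (!is.null(prev_scales) && m %in% names(prev_scales))
      sc[m] <- prev_scales[[m]]
  }
  sc
}

#' Multimodal nonlinear registration
#'
#' Multiresolution descent minimising the weighted sum of the per-channel
#' data costs plus bending-energy regularisation. The displacement is
#' parameterised on each level's knot grid (trilinear basis); images are
#' smoothed by the level's FWHM. The returned warp is the nonlinear part
#' only (the affine `init` is composed during evaluation but excluded from
#' the result). Deterministic.
#'
#' @param subject,template lists with `t1`, `flair` (`ScalarImage`) and
#'   optionally `dti` (`TensorImage`).
#' @param params `RegParams`.
#' @param init `AffineTransform` mapping template space to subject space.
#' @param weight_masks list with optional `t1` and `dti` `WeightImage`s in
#'   template space.
#' @param use_dti include the tensor channel (default: present in both).
#' @param verbose print per-level costs.
#' @param cost_floor_rel fraction of each channel's squared intensity scale
#'   used as the rescaling floor (see [rescale_channel_costs()]).
#' @return `RegResult`: list with `warp` (`DisplacementField`),
#'   `final_costs`, and `trace` (total cost per accepted iteration).
#' @export
register_multimodal <- function(subject, template, params = reg_params(),
                                init = affine_identity(),
                                weight_masks = list(), use_dti = NULL,
                                verbose = FALSE, cost_floor_rel = 1e-3) {
  grid <- template$t1$grid
  sgrid <- subject$t1$grid
  scales <- NULL
  if (is.null(use_dti))
    use_dti <- !is.null(subject$dti) && !is.null(template$dti)
  lam <- params$lambda
  wt1 <- weights_or_one(weight_masks$t1, grid)
  wfl <- array(1, grid$shape)
  wdt <- if (use_dti) as.numeric(weights_or_one(weight_masks$dti, grid)) else NULL
  if (sum(wt1) == 0) stop("all-zero weights")
  x <- grid_world_coords(grid)
  trace <- list()
  kgrid <- NULL; coef <- NULL
  Blin <- init$matrix[1:3, 1:3]
  boff <- init$matrix[1:3, 4]

  for (lev in seq_len(nrow(params$schedule))) {
    sp <- params$schedule$spacing_mm[lev]
    fw <- params$schedule$fwhm_mm[lev]
    iters <- params$schedule$iters[lev]
    new_kgrid <- make_knot_grid(grid, sp)
    if (is.null(coef)) {
      coef <- matrix(0, n_voxels(new_kgrid), 3)
    } else {
      prev_field <- array(coef, dim = c(kgrid$shape, 3L))
      kv <- world_to_voxel_points(kgrid, grid_world_coords(new_kgrid))
      nc <- matrix(0, n_voxels(new_kgrid), 3)
      for (k in 1:3)
        nc[, k] <- interp_at_voxels(prev_field[, , , k], kv, order = 1,
                                    oob = "clamp")$values
      coef <- nc
    }
    kgrid <- new_kgrid

    st1 <- smooth_image(subject$t1, fw); tt1 <- smooth_image(template$t1, fw)
    sfl <- smooth_image(subject$flair, fw); tfl <- smooth_image(template$flair, fw)
    tmpl_sc <- list(t1 = tt1$values, flair = tfl$values)
    subj_sc <- list(t1 = st1$values, flair = sfl$values)
    subj_gr <- list(t1 = grad_volumes(st1$values), flair = grad_volumes(sfl$values))
    subj_cols <- lapply(names(subj_sc), function(ch)
      cbind(as.numeric(subj_sc[[ch]]), subj_gr[[ch]][[1]], subj_gr[[ch]][[2]],
            subj_gr[[ch]][[3]]))
    names(subj_cols) <- names(subj_sc)
    wsc <- list(t1 = as.numeric(wt1), flair = as.numeric(wfl))

    if (use_dti) {
      # smooth tensor components with the level's kernel (component-wise,
      # Euclidean: adequate for the data term's capture range)
      smooth6 <- function(t6, grd) {
        if (fw <= 0) return(t6)
        sv <- fwhm_to_sigma(fw) / mean(grid_voxel_size(grd))
        apply(t6, 2, function(v) as.numeric(gauss_smooth3(array(v, grd$shape), sv)))
      }
      subj_dt6 <- smooth6(tensor_matrix(subject$dti), sgrid)
      tmpl_dt6 <- smooth6(tensor_matrix(template$dti), grid)
      # finite-strain reorientation, refreshed once per level: comparing
      # R D_S R^T with D_T is equivalent to comparing D_S with R^T D_T R,
      # so the template tensors are rotated by the transpose of the current
      # total map's finite-strain rotation (identity at the first level when
      # the initial transform is rigid-free)
      tmpl_dt6 <- reorient_template_tensors(tmpl_dt6, coef, kgrid, grid, x, Blin)
      tmpl_dvalid <- as.logical(template$dti$valid)
      subj_dvalid <- array(as.numeric(subject$dti$valid), sgrid$shape)
      subj_dgr <- lapply(1:6, function(k)
        grad_volumes(array(subj_dt6[, k], sgrid$shape)))
      dti_cols <- cbind(subj_dt6, as.numeric(subj_dvalid),
                        do.call(cbind, lapply(subj_dgr, function(g)
                          cbind(as.numeric(g[[1]]), as.numeric(g[[2]]),
                                as.numeric(g[[3]])))))
    }

    # per-level channel rescaling at the current iterate
    eval_data <- function(cf) {
      d <- knots_field_disp(kgrid, cf, x, grid)
      pts <- sweep((x + d) %*% t(Blin), 2, boff, `+`)
      data_costs_and_grads(pts, grid, subj_sc, tmpl_sc, wsc,
                           if (use_dti) list(t6 = tmpl_dt6,
                                             tvalid = tmpl_dvalid,
                                             w = wdt, cols = dti_cols)
                           else NULL,
                           Blin, grad = FALSE, sgrid = sgrid,
                           scols = subj_cols)
    }
    # per-level channel rescaling at the current iterate, with floors at a
    # small fraction of each channel's squared intensity scale so that an
    # already-matched channel cannot be inflated into dominance
    floors <- c(t1 = cost_floor_rel * mean(wsc$t1 * as.numeric(tmpl_sc$t1)^2) / mean(wsc$t1),
                flair = cost_floor_rel * mean(as.numeric(tmpl_sc$flair)^2))
    if (use_dti) {
      fl_d <- frob2_rows(tmpl_dt6)
      floors["dti"] <- cost_floor_rel *
        sum(wdt * tmpl_dvalid * fl_d) / max(sum(wdt * tmpl_dvalid), 1)
    }
    scales <- rescale_channel_costs(eval_data(coef)$costs, scales, floors)

    obj <- function(cf, grad = TRUE) {
      d <- knots_field_disp(kgrid, cf, x, grid)
      pts <- sweep((x + d) %*% t(Blin), 2, boff, `+`)
      ev <- data_costs_and_grads(pts, grid, subj_sc, tmpl_sc, wsc,
                                 if (use_dti) list(t6 = tmpl_dt6,
                                                   tvalid = tmpl_dvalid,
                                                   w = wdt, cols = dti_cols)
                                 else NULL,
                                 Blin, grad = grad, sgrid = sgrid,
                                 scols = subj_cols)
      tot <- lam[["t1"]] * scales[["t1"]] * ev$costs$t1 +
        lam[["flair"]] * scales[["flair"]] * ev$costs$flair +
        (if (use_dti) lam[["dti"]] * scales[["dti"]] * ev$costs$dti else 0) +
        lam[["reg"]] * bending_energy(kgrid, cf) * mean(grid_voxel_size(kgrid))^4
      out <- list(total = tot, costs = ev$costs)
      if (grad) {
        gd <- lam[["t1"]] * scales[["t1"]] * ev$grads$t1 +
          lam[["flair"]] * scales[["flair"]] * ev$grads$flair
        if (use_dti) gd <- gd + lam[["dti"]] * scales[["dti"]] * ev$grads$dti
        gk <- dense_grad_to_knots(kgrid, grid, gd)
        gk <- gk + lam[["reg"]] * bending_gradient(kgrid, cf) *
          mean(grid_voxel_size(kgrid))^4
        out$grad <- gk
      }
      out
    }

    cur <- obj(coef)
    if (!is.finite(cur$total))
      stop(sprintf("non-finite cost at level %d start", lev))
    step <- 1
    for (it in seq_len(iters)) {
      g <- cur$grad
      gmax <- max(abs(g))
      if (gmax < 1e-12) break
      # normalise so the step is in mm at the knots
      dir <- -g / gmax
      accepted <- FALSE
      for (ls in 1:8) {
        cand <- coef + step * dir
        nxt <- obj(cand, grad = FALSE)
        if (is.finite(nxt$total) && nxt$total < cur$total) {
          coef <- cand
          cur <- obj(cand, grad = TRUE)
          accepted <- TRUE
          step <- step * 1.5
          break
        }
        step <- step / 2
      }
      trace[[length(trace) + 1L]] <- data.frame(level = lev, iter = it,
                                                total = cur$total)
      if (!accepted) break
    }
    if (verbose)
      message(sprintf("level %d (%.3g mm): total %.5g  t1 %.4g flair %.4g dti %.4g",
                      lev, sp, cur$total, cur$costs$t1, cur$costs$flair,
                      if (use_dti) cur$costs$dti else NA))
  }
  warp <- knots_to_field(kgrid, coef, grid)
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(level = integer(), iter = integer(), total = numeric())
  structure(list(warp = warp, final_costs = cur$costs, trace = trace),
            class = "RegResult")
}

knots_field_disp <- function(kgrid, coef, x, grid) {
  vox <- world_to_voxel_points(kgrid, x)
  interp3_multi_cpp(coef, as.integer(kgrid$shape), vox, 1L)
}

# data costs and dense gradients wrt the displacement (template-grid voxels).
# pts: native-space sample points (after affine). Gradients are chain-ruled
# through the affine linear part Blin.
data_costs_and_grads <- function(pts, grid, subj_sc, tmpl_sc, wsc, dti, Blin,
                                 grad = TRUE, sgrid = grid, scols = NULL) {
  costs <- list(); grads <- list()
  vox <- world_to_voxel_points(sgrid, pts)
  Ainv3 <- solve(sgrid$voxel_to_world)[1:3, 1:3]
  for (ch in names(tmpl_sc)) {
    if (!is.null(scols)) {
      ncol_use <- if (grad) 4L else 1L
      smp <- interp3_multi_cpp(scols[[ch]][, seq_len(ncol_use), drop = FALSE],
                               as.integer(sgrid$shape), vox, 0L)
      pred <- smp[, 1]
      gimg <- if (grad) smp[, 2:4, drop = FALSE] %*% Ainv3 else NULL
    } else {
      pred <- interp_at_voxels(array(subj_sc[[ch]], sgrid$shape), vox, 1, "zero")$values
      gimg <- if (grad) numeric_gradient_at(subj_sc[[ch]], sgrid, vox) else NULL
    }
    resid <- pred - as.numeric(tmpl_sc[[ch]])
    w <- wsc[[ch]]
    sw <- sum(w)
    costs[[ch]] <- sum(w * resid^2) / sw
    if (grad) {
      gw <- (2 / sw) * w * resid
      grads[[ch]] <- cbind(gw * gimg[, 1], gw * gimg[, 2], gw * gimg[, 3]) %*% Blin
    }
  }
  if (!is.null(dti)) {
    ncol_use <- if (grad) ncol(dti$cols) else 7L
    smp <- interp3_multi_cpp(dti$cols[, seq_len(ncol_use), drop = FALSE],
                             as.integer(sgrid$shape), vox, 0L)
    pred6 <- smp[, 1:6, drop = FALSE]
    vfrac <- smp[, 7]
    use <- dti$tvalid & vfrac > 0.99
    resid6 <- pred6 - dti$t6
    wv <- dti$w * use
    sw <- sum(wv)
    fmul <- c(1, 2, 2, 1, 2, 1) # Frobenius multiplicities
    costs$dti <- if (sw > 0) sum(wv * frob2_rows(resid6)) / sw else 0
    if (grad) {
      gdense <- matrix(0, nrow(vox), 3)
      if (sw > 0) {
        for (k in 1:6) {
          gk <- smp[, 7 + (k - 1) * 3 + 1:3, drop = FALSE] %*% Ainv3
          gw <- (2 * fmul[k] / sw) * wv * resid6[, k]
          gdense <- gdense + cbind(gw * gk[, 1], gw * gk[, 2], gw * gk[, 3])
        }
        gdense <- gdense %*% Blin
      }
      grads$dti <- gdense
    }
  }
  list(costs = costs, grads = grads)
}

# central-difference spatial gradient of a volume sampled at continuous voxel
# coordinates, returned in world units (N x 3)
numeric_gradient_at <- function(vol, grid, vox) {
  vol <- array(vol, grid$shape)
  g <- matrix(0, nrow(vox), 3)
  Ainv <- solve(grid$voxel_to_world)[1:3, 1:3]
  for (l in 1:3) {
    e <- matrix(0, 1, 3); e[l] <- 0.5
    vp <- sweep(vox, 2, -e[1, ])   # vox + 0.5 e_l
    vm <- sweep(vox, 2, e[1, ])
    g[, l] <- interp_at_voxels(vol, vp, 1, "clamp")$values -
      interp_at_voxels(vol, vm, 1, "clamp")$values
  }
  # d/dindex -> d/dworld: grad rows times Ainv
  g %*% Ainv
}

# precompute voxel-index central-difference gradient volumes of an image
grad_volumes <- function(vol) lapply(1:3, function(l) array_diff(vol, l))

# interpolate precomputed gradient volumes at continuous voxel coordinates,
# returning world-unit gradients (N x 3)
sampled_gradient <- function(gvols, grid, vox) {
  g <- matrix(0, nrow(vox), 3)
  for (l in 1:3)
    g[, l] <- interp_at_voxels(gvols[[l]], vox, 1, "clamp")$values
  g %*% solve(grid$voxel_to_world)[1:3, 1:3]
}


# rotate template tensors by the transpose of the finite-strain rotation of
# the current total map x -> B(x + d(x)); rows with singular local Jacobians
# keep their original tensors
reorient_template_tensors <- function(t6, coef, kgrid, grid, x, Blin) {
  d <- knots_field_disp(kgrid, coef, x, grid)
  J <- warp_jacobian_matrices(displacement_field(grid, d))
  # row-wise left-multiply by Blin (column-major 3x3 per row)
  JB <- matrix(0, nrow(J), 9)
  for (cc in 1:3) for (rr in 1:3) {
    acc <- 0
    for (k in 1:3) acc <- acc + Blin[rr, k] * J[, (cc - 1) * 3 + k]
    JB[, (cc - 1) * 3 + rr] <- acc
  }
  if (max(abs(sweep(JB, 2, as.numeric(diag(3))))) < 1e-12) return(t6)
  Minv <- invert3_rows(JB)
  fs <- finite_strain_batch(Minv$inv)
  ok <- Minv$ok & fs$valid
  # transpose each rotation (column-major row storage: permute entries)
  Rt <- fs$rot[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]
  out <- t6
  if (any(ok)) {
    pp <- ppd_reorient_batch(t6[ok, , drop = FALSE], Rt[ok, , drop = FALSE])
    rows <- which(ok)
    out[rows[pp$valid], ] <- pp$tensors[pp$valid, , drop = FALSE]
  }
  out
}
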