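# Gaussian-process modelling of deformation fields versus age, and
# age-dependent template generation.
#
# Each displacement component at each voxel is an independent GP output over
# age; all outputs share one squared-exponential kernel and one noise scale.
# Training data are stratified into half-yearly age bins, each split into
# two randomly assigned sub-bins whose member warps are averaged; the noise
# covariance is sigma_n^2 W with W = diag(1/p_l) so sub-bins pooled from
# more subjects carry less noise.

#' Stratify ages and warps into half-yearly sub-bins
#'
#' Ages are cut into half-open half-yearly bins over `[age_low, age_high)`;
#' within each bin every subject is randomly assigned to one of
#' `subbins_per_bin` sub-bins. Per nonempty sub-bin the mean age, the count
#' `p_l` and the Euclidean mean displacement field are recorded; empty
#' sub-bins are dropped. Only the nonlinear parts of the warps should be
#' supplied (brain-size differences are not modelled).
#'
#' @param ages numeric vector of subject ages.
#' @param warps list of `DisplacementField`s, one per subject, common grid.
#' @param age_low,age_high stratification range; defaults to the floor/ceiling
#'   half-year enclosing the observed ages.
#' @param bin_width bin width in years (default 0.5).
#' @param subbins_per_bin sub-bins per bin (default 2).
#' @param seed RNG seed for the random sub-bin assignment.
#' @return `StratifiedTraining`: list with `x_bar` (mean ages), `p` (counts),
#'   `Y_bar` (L x 3V matrix of mean displacement components), `W_diag`
#'   (`1/p`), `grid`, `n_bins`, `n_subbins_total`, `assignment`.
#' @export
stratify_training <- function(ages, warps = NULL, age_low = NULL,
                              age_high = NULL, bin_width = 0.5,
                              subbins_per_bin = 2L, seed = 1L) {
  n <- length(ages)
  if (n == 0L) stop("no subjects to stratify")
  if (!is.null(warps)) stopifnot(length(warps) == n)
  if (is.null(age_low)) age_low <- floor(min(ages) / bin_width) * bin_width
  if (is.null(age_high)) age_high <- ceiling(max(ages) / bin_width + 1e-9) * bin_width
  if (max(ages) >= age_high) age_high <- age_high + bin_width
  n_bins <- round((age_high - age_low) / bin_width)
  bin <- pmin(pmax(floor((ages - age_low) / bin_width), 0), n_bins - 1)
  set.seed(seed)
  sub <- sample.int(subbins_per_bin, n, replace = TRUE)
  key <- bin * subbins_per_bin + (sub - 1L)        # 0-based sub-bin id
  ids <- sort(unique(key))
  L <- length(ids)
  x_bar <- numeric(L); p <- integer(L)
  grid <- if (!is.null(warps)) warps[[1]]$grid else NULL
  Y_bar <- if (!is.null(warps)) matrix(0, L, 3 * n_voxels(grid)) else NULL
  for (l in seq_len(L)) {
    members <- which(key == ids[l])
    x_bar[l] <- mean(ages[members])
    p[l] <- length(members)
    if (!is.null(warps)) {
      acc <- 0
      for (m in members) {
        stop_if_grid_mismatch(grid, warps[[m]]$grid, "warps")
        acc <- acc + as.numeric(warps[[m]]$disp)
      }
      Y_bar[l, ] <- acc / p[l]
    }
  }
  structure(list(x_bar = x_bar, p = p, Y_bar = Y_bar, W_diag = 1 / p,
                 grid = grid, n_bins = n_bins,
                 n_subbins_total = n_bins * subbins_per_bin,
                 L = L, assignment = key, age_low = age_low,
                 age_high = age_high, bin_width = bin_width),
            class = "StratifiedTraining")
}

#' Squared-exponential kernel
#'
#' `k(x, x') = sigma_f^2 exp(-(x - x')^2 / (2 l^2))`.
#' @param x,xp numeric vectors of ages (cross-covariance matrix returned).
#' @param hyper list/vector with `sigma_f`, `sigma_n`, `ell` (only `sigma_f`
#'   and `ell` are used here).
#' @export
sq_exp_kernel <- function(x, xp, hyper) {
  d <- outer(x, xp, `-`)
  hyper[["sigma_f"]]^2 * exp(-d^2 / (2 * hyper[["ell"]]^2))
}

#' GP hyperparameters
#' @param sigma_f signal scale (mm).
#' @param sigma_n noise scale (mm).
#' @param ell length scale (years).
#' @export
gp_hyperparams <- function(sigma_f, sigma_n, ell) {
  stopifnot(sigma_f > 0, sigma_n > 0, ell > 0)
  list(sigma_f = sigma_f, sigma_n = sigma_n, ell = ell)
}

gp_gram <- function(hyper, training, jitter = 1e-8) {
  K <- sq_exp_kernel(training$x_bar, training$x_bar, hyper)
  K + diag(hyper[["sigma_n"]]^2 * training$W_diag +
             jitter * hyper[["sigma_f"]]^2, training$L)
}

#' Negative log marginal likelihood of the deformation GP
#'
#' `0.5 y^T (K + sigma_n^2 W)^{-1} y + 0.5 log|K + sigma_n^2 W|` summed over
#' the sampled voxel components (independent outputs, shared
#' hyperparameters). The `L/2 log(2 pi)` constant is dropped consistently.
#'
#' @param hyper `gp_hyperparams()` result.
#' @param training `StratifiedTraining`.
#' @param voxel_sample integer indices of columns of `Y_bar` to use
#'   (default: all).
#' @export
gp_neg_log_marginal_likelihood <- function(hyper, training, voxel_sample = NULL) {
  Kn <- gp_gram(hyper, training)
  ch <- tryCatch(chol(Kn), error = function(e)
    stop(sprintf("Gram factorisation failed at sigma_f=%.3g sigma_n=%.3g ell=%.3g",
                 hyper[["sigma_f"]], hyper[["sigma_n"]], hyper[["ell"]])))
  Y <- training$Y_bar
  if (!is.null(voxel_sample)) Y <- Y[, voxel_sample, drop = FALSE]
  alpha <- backsolve(ch, forwardsolve(t(ch), Y))
  quad <- sum(Y * alpha)
  logdet <- 2 * sum(log(diag(ch)))
  0.5 * quad + 0.5 * ncol(Y) * logdet
}

#' Fit GP hyperparameters by Nelder-Mead
#'
#' Derivative-free simplex minimisation of the negative log marginal
#' likelihood over `(log sigma_f, log sigma_n, log ell)`, evaluated on a
#' random subsample of in-brain voxel components drawn once from `seed`.
#' Initialisation (when not given): `sigma_f` = standard deviation of the
#' training displacement components, `sigma_n = 0.5 sigma_f`, `ell` = 10
#' years.
#'
#' @param training `StratifiedTraining`.
#' @param n_voxels number of voxel components sampled (default 10000).
#' @param seed RNG seed for the subsample.
#' @param init optional initial `gp_hyperparams()`.
#' @param brain_mask optional logical/0-1 array on the training grid
#'   restricting the sample to in-brain voxels.
#' @param reltol simplex convergence tolerance in log-space.
#' @param maxit evaluation cap; non-convergence returns the best point with
#'   attribute `"converged" = FALSE` and a warning.
#' @return `gp_hyperparams()` list with attributes `"value"`, `"converged"`,
#'   `"voxel_sample"`.
#' @export
fit_hyperparameters <- function(training, n_voxels = 10000L, seed = 1L,
                                init = NULL, brain_mask = NULL,
                                reltol = 1e-8, maxit = 500L) {
  V3 <- ncol(training$Y_bar)
  pool <- seq_len(V3)
  if (!is.null(brain_mask)) {
    bm <- if (inherits(brain_mask, "ScalarImage")) brain_mask$values > 0.5 else brain_mask
    pool <- which(rep(as.logical(bm), 3L))
  }
  set.seed(seed)
  vs <- if (length(pool) > n_voxels) sort(sample(pool, n_voxels)) else pool
  if (is.null(init)) {
    s <- sd(training$Y_bar[, vs])
    if (!is.finite(s) || s <= 0) s <- 1
    init <- gp_hyperparams(s, 0.5 * s, 10)
  }
  p0 <- log(c(init$sigma_f, init$sigma_n, init$ell))
  nll <- function(lp) {
    h <- gp_hyperparams(exp(lp[1]), exp(lp[2]), exp(lp[3]))
    tryCatch(gp_neg_log_marginal_likelihood(h, training, vs),
             error = function(e) 1e300)
  }
  opt <- optim(p0, nll, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol))
  conv <- opt$convergence == 0
  if (!conv) warning("hyperparameter fit did not converge; returning best point")
  out <- gp_hyperparams(exp(opt$par[1]), exp(opt$par[2]), exp(opt$par[3]))
  attr(out, "value") <- opt$value
  attr(out, "converged") <- conv
  attr(out, "voxel_sample") <- vs
  out
}

#' Assemble a GP model with a cached factorisation
#'
#' @param training `StratifiedTraining` (with `Y_bar`).
#' @param hyper `gp_hyperparams()`.
#' @return `GPModel` with the Cholesky factor of `K + sigma_n^2 W` cached.
#' @export
gp_model <- function(training, hyper) {
  Kn <- gp_gram(hyper, training)
  structure(list(training = training, hyper = hyper, chol = chol(Kn)),
            class = "GPModel")
}

#' Predictive mean deformation field at an age
#'
#' `y* = k(x*, x_bar) (K + sigma_n^2 W)^{-1} Y_bar`, one cached solve reused
#' across all voxel components. Far from the training ages the prediction
#' reverts to the zero prior mean.
#'
#' @param age_star query age (years). Prediction outside the training range
#'   is permitted but triggers a warning.
#' @param model `GPModel`.
#' @return `DisplacementField` on the training grid.
#' @export
gp_predict_mean_field <- function(age_star, model) {
  tr <- model$training
  if (age_star < min(tr$x_bar) - 1e-9 || age_star > max(tr$x_bar) + 1e-9)
    warning("predicting outside the training age range: the field shrinks toward the prior mean")
  k <- as.numeric(sq_exp_kernel(age_star, tr$x_bar, model$hyper))
  ch <- model$chol
  w <- backsolve(ch, forwardsolve(t(ch), k))     # (K + sn^2 W)^{-1} k
  ystar <- as.numeric(crossprod(tr$Y_bar, w))
  displacement_field(tr$grid, ystar)
}

#' Generate an age-dependent template
#'
#' The GP-predicted mean field at `age_star` is inverted and composed with
#' each construction subject's full (unbiased) transform,
#' `x -> full_n(pred^{-1}(x))`, before resampling that subject's native
#' channels to age-specific template space in one step and averaging as in
#' the templating loop. Intensities therefore derive only from the
#' construction cohort. Diffeomorphism of the predicted warp is checked
#' empirically: a non-positive minimum Jacobian proceeds with a warning.
#'
#' @param age_star target age in years.
#' @param model `GPModel` fitted on warps in fixed-template space.
#' @param fixed_template `MultimodalTemplate`.
#' @param subject_warps construction cohort's full composed warps (one per
#'   subject, fixed-template grid).
#' @param cohort construction `SyntheticCohort`.
#' @return `MultimodalTemplate` with attributes `"min_jacobian"` and
#'   `"pred_field"`.
#' @export
make_age_template <- function(age_star, model, fixed_template, subject_warps,
                              cohort) {
  pred <- gp_predict_mean_field(age_star, model)
  minj <- min(jacobian_determinant_map(pred)$values)
  if (minj <= 0)
    warning(sprintf("predicted warp is not diffeomorphic (min Jacobian %.3g)", minj))
  grid <- fixed_template$t1$grid
  pred_inv <- invert_warp(pred, tol = 0.05 * min(grid_voxel_size(grid)),
                          max_iter = 100)
  subs <- cohort$subjects
  resampled <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    comp <- compose_warps(subject_warps[[i]], pred_inv)
    resampled[[i]] <- resample_subject_all(subs[[i]], comp)
  }
  out <- average_resampled(resampled, grid, fixed_template$iteration)
  attr(out, "min_jacobian") <- minj
  attr(out, "pred_field") <- pred
  out
}

#' Save / load a GP model as JSON + NIfTI
#'
#' Hyperparameters, training ages and counts go to `model.json`; the
#' training mean fields to one NIfTI per sub-bin.
#' @param model `GPModel`.
#' @param dir output directory.
#' @export
write_gp_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- model$training
  meta <- list(hyper = model$hyper[c("sigma_f", "sigma_n", "ell")],
               x_bar = tr$x_bar, p = tr$p,
               grid = list(shape = tr$grid$shape,
                           voxel_to_world = as.numeric(tr$grid$voxel_to_world)))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  for (l in seq_len(tr$L)) {
    f <- displacement_field(tr$grid, tr$Y_bar[l, ])
    write_field_nifti(f, file.path(dir, sprintf("ybar_%04d.nii.gz", l)))
  }
  invisible(dir)
}

#' @rdname write_gp_model
#' @export
read_gp_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  grid <- image_grid(meta$grid$shape, matrix(meta$grid$voxel_to_world, 4, 4))
  L <- length(meta$x_bar)
  Y <- matrix(0, L, 3 * n_voxels(grid))
  for (l in seq_len(L)) {
    f <- read_field_nifti(file.path(dir, sprintf("ybar_%04d.nii.gz", l)))
    Y[l, ] <- as.numeric(f$disp)
  }
  training <- structure(list(x_bar = meta$x_bar, p = meta$p, Y_bar = Y,
                             W_diag = 1 / meta$p, grid = grid, L = L),
                        class = "StratifiedTraining")
  gp_model(training, gp_hyperparams(meta$hyper$sigma_f, meta$hyper$sigma_n,
                                    meta$hyper$ell))
}
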