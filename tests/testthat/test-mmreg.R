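make_reg_pair <- function(noise = 5) {
  p <- small_phantom_params(noise_sd = list(t1 = noise, flair = noise, dti = 0))
  can <- make_canonical_anatomy(p)
  list(p = p, can = can,
       tmpl = list(t1 = can$t1, flair = can$flair, dti = can$dti))
}

test_that("channel costs match hand-computed values", {
  fx <- make_reg_pair(0)
  g <- fx$can$t1$grid
  # identical images, zero warp: all data costs zero
  cc <- channel_costs(fx$tmpl, fx$tmpl, zero_field(g))
  expect_equal(cc$t1, 0); expect_equal(cc$flair, 0); expect_equal(cc$dti, 0)
  # constant intensity offset c with uniform unit weights: MSE = c^2
  sub2 <- fx$tmpl
  sub2$t1 <- scalar_image(g, fx$can$t1$values + 12)
  cc2 <- channel_costs(sub2, fx$tmpl, zero_field(g))
  expect_equal(cc2$t1, 144, tolerance = 1e-9)
  # single-voxel tensor difference diag(1,0,0) vs diag(0,1,0): Frobenius^2 = 2
  gg <- tiny_grid(4, 1)
  t1v <- scalar_image(gg, array(1, gg$shape))
  ta <- matrix(0, 64, 6); ta[, c(1, 4, 6)] <- 1e-3   # PD background
  tb <- ta
  ta[30, ] <- c(1, 0, 0, 0, 0, 0); tb[30, ] <- c(0, 0, 0, 1, 0, 0)
  A <- list(t1 = t1v, flair = t1v, dti = tensor_image(gg, ta))
  B <- list(t1 = t1v, flair = t1v, dti = tensor_image(gg, tb))
  ccT <- channel_costs(A, B, zero_field(gg))
  # weighted mean over valid voxels: one voxel contributes 2, rest 0
  nvalid <- sum(B$dti$valid & A$dti$valid)
  expect_equal(ccT$dti, 2 / nvalid, tolerance = 1e-6)
  expect_error(channel_costs(A, B, zero_field(gg),
                             weight_masks = list(t1 = weight_image(gg, array(0, gg$shape)))),
               "all-zero")
})

test_that("channel cost rescaling equalises contributions and freezes zeros", {
  costs <- list(t1 = 2, flair = 4, dti = 8)
  sc <- rescale_channel_costs(costs)
  expect_equal(unname(sc["t1"] * costs$t1), 1)
  expect_equal(unname(sc["flair"] * costs$flair), 1)
  expect_equal(unname(sc["dti"] * costs$dti), 1)
  sc2 <- rescale_channel_costs(list(t1 = 0, flair = 3),
                               prev_scales = c(t1 = 7, flair = 1))
  expect_equal(unname(sc2["t1"]), 7)
})

test_that("registering an image to itself stays near the identity", {
  fx <- make_reg_pair(0)
  rr <- register_multimodal(fx$tmpl, fx$tmpl,
                            reg_params(schedule = default_reg_schedule(2, 10)))
  expect_lte(max(abs(rr$warp$disp)), 0.25 * 3)   # <= 0.25 voxel
})

test_that("registration recovers a known smooth warp and is cost-monotone", {
  fx <- make_reg_pair(0)
  g <- fx$can$t1$grid
  truth <- omtemplate:::random_smooth_field(g, 4, 14, seed = 31)
  subj <- list(t1 = resample_scalar(fx$can$t1, truth, 3),
               flair = resample_scalar(fx$can$flair, truth, 3),
               dti = resample_tensor(fx$can$dti, truth))
  rr <- register_multimodal(subj, fx$tmpl,
                            reg_params(schedule = default_reg_schedule(3, 20)))
  truth_inv <- invert_warp(truth, tol = 0.005, max_iter = 100)
  err <- field_mag(displacement_field(g, rr$warp$disp - truth_inv$disp))
  base <- field_mag(truth_inv)
  brain <- in_brain_idx(fx$can)
  expect_lte(mean(err[brain]), 3)                 # <= 1 voxel mean EPE
  expect_lt(mean(err[brain]), 0.8 * mean(base[brain]))  # better than no-op
  for (lv in unique(rr$trace$level)) {            # monotone within a level
    tot <- rr$trace$total[rr$trace$level == lv]
    expect_true(all(diff(tot) <= 1e-12))
  }
})

test_that("optimisation is invariant to a global intensity/cost scaling", {
  fx <- make_reg_pair(0)
  g <- fx$can$t1$grid
  truth <- omtemplate:::random_smooth_field(g, 3, 14, seed = 32)
  subj <- list(t1 = resample_scalar(fx$can$t1, truth, 3),
               flair = resample_scalar(fx$can$flair, truth, 3))
  tmpl <- list(t1 = fx$tmpl$t1, flair = fx$tmpl$flair)
  prm <- reg_params(schedule = default_reg_schedule(2, 8))
  r1 <- register_multimodal(subj, tmpl, prm, use_dti = FALSE)
  scale_img <- function(im, s) scalar_image(im$grid, im$values * s)
  subj2 <- list(t1 = scale_img(subj$t1, 10), flair = scale_img(subj$flair, 10))
  tmpl2 <- list(t1 = scale_img(tmpl$t1, 10), flair = scale_img(tmpl$flair, 10))
  r2 <- register_multimodal(subj2, tmpl2, prm, use_dti = FALSE)
  # identical trajectory (up to IEEE rounding of the cost rescaling)
  expect_equal(r1$warp$disp, r2$warp$disp, tolerance = 1e-12)
})

test_that("inverse-consistency proxy: A->B and B->A compositions stay sub-voxel", {
  fx <- make_reg_pair(0)
  g <- fx$can$t1$grid
  truth <- omtemplate:::random_smooth_field(g, 3, 16, seed = 33)
  A <- fx$tmpl[c("t1", "flair")]
  B <- list(t1 = resample_scalar(fx$can$t1, truth, 3),
            flair = resample_scalar(fx$can$flair, truth, 3))
  prm <- reg_params(schedule = default_reg_schedule(3, 15))
  wab <- register_multimodal(B, A, prm, use_dti = FALSE)$warp   # A-space -> B
  wba <- register_multimodal(A, B, prm, use_dti = FALSE)$warp   # B-space -> A
  comp <- compose_warps(wba, wab)
  brain <- in_brain_idx(fx$can)
  expect_lte(max(field_mag(comp)[brain]), 3)      # <= 1 voxel in-brain
})

test_that("the tensor channel drives alignment where scalars are uninformative", {
  # two phantoms whose scalar channels agree (WM intensity is uniform) but
  # whose tract arcs are tilted copies: DTI-informed registration must
  # reduce the tensor cost substantially below scalar-only registration
  # needs the default desk resolution so the tract tube is resolved
  p <- phantom_params(noise_sd = list(t1 = 0, flair = 0, dti = 0))
  can <- make_canonical_anatomy(p)
  g <- can$t1$grid
  pts <- omtemplate:::grid_world_coords(g)
  th <- 12 * pi / 180
  Rz <- omtemplate:::rot3(3, th)
  rot_dti <- omtemplate:::phantom_tensors(pts %*% Rz, p)
  pp <- omtemplate:::ppd_reorient_batch(
    rot_dti$tensors, matrix(rep(as.numeric(t(Rz)), each = nrow(pts)), nrow(pts), 9))
  tens <- pp$tensors
  vent <- omtemplate:::phantom_vent_frac(pts, p, 1, 0.9) > 0.5
  tens[vent, ] <- omtemplate:::tensor_matrix(can$dti)[vent, ]
  subj <- list(t1 = can$t1, flair = can$flair,
               dti = tensor_image(g, tens,
                                  valid = array(rot_dti$valid | can$dti$valid, g$shape)))
  tmpl <- list(t1 = can$t1, flair = can$flair, dti = can$dti)
  prm <- reg_params(schedule = default_reg_schedule(4, 25))
  r_dti <- register_multimodal(subj, tmpl, prm, use_dti = TRUE)
  r_sc <- register_multimodal(subj, tmpl, prm, use_dti = FALSE)
  cost_with <- channel_costs(subj, tmpl, r_dti$warp)$dti
  cost_without <- channel_costs(subj, tmpl, r_sc$warp)$dti
  expect_lt(cost_with, 0.5 * cost_without)
})

test_that("backend contract: imported warp files behave like computed ones", {
  fx <- make_reg_pair(0)
  g <- fx$can$t1$grid
  rr <- register_multimodal(fx$tmpl, fx$tmpl,
                            reg_params(schedule = default_reg_schedule(1, 3)))
  td <- withr::local_tempdir()
  f <- file.path(td, "warp.nii.gz")
  write_field_nifti(rr$warp, f)
  imported <- read_field_nifti(f)
  expect_equal(imported$disp, rr$warp$disp, tolerance = 1e-14)
  expect_true(omtemplate:::grid_equal(imported$grid, g))
  # grid mismatch on import is an error at composition time
  other <- zero_field(tiny_grid(8))
  expect_error(mean_warp(list(imported, other)), "grid mismatch")
})

test_that("the 8:1 weight mask concentrates displacement inside the brain", {
  # equal in/out mismatch: the subject is the template under one global
  # smooth warp; with the 8:1 intracranial weighting the recovered
  # extracranial displacement must not exceed the intracranial one
  fx <- make_reg_pair(0)
  g <- fx$can$t1$grid
  truth <- omtemplate:::random_smooth_field(g, 3, 16, seed = 55)
  subj <- list(t1 = resample_scalar(fx$can$t1, truth, 3),
               flair = resample_scalar(fx$can$flair, truth, 3))
  tmpl <- list(t1 = fx$tmpl$t1, flair = fx$tmpl$flair)
  wmask <- make_weight_mask(weight_image(g, fx$can$brain_mask$values))
  rr <- register_multimodal(subj, tmpl,
                            reg_params(schedule = default_reg_schedule(3, 15)),
                            weight_masks = list(t1 = wmask), use_dti = FALSE)
  mag <- field_mag(rr$warp)
  inb <- in_brain_idx(fx$can)
  head <- as.numeric(fx$can$t1$values) > 10      # restrict "out" to the head
  out <- head & !inb
  expect_lte(mean(mag[out]), mean(mag[inb]))
})
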