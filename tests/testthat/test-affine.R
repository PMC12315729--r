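test_that("midspace transforms satisfy the log-mean identity contract", {
  # all-identity input
  ids <- lapply(1:3, function(i) affine_identity())
  out <- midspace_transforms(ids)
  for (m in out) expect_equal(m$matrix, diag(4), tolerance = 1e-12)
  # two opposite translations: relative geometry preserved, log-mean zero
  tr <- function(t) affine_transform(rbind(cbind(diag(3), t), c(0, 0, 0, 1)))
  out2 <- midspace_transforms(list(tr(c(4, 0, 0)), tr(c(-4, 0, 0))))
  expect_equal(out2[[1]]$matrix[1:3, 4], c(4, 0, 0), tolerance = 1e-9)
  expect_equal(out2[[2]]$matrix[1:3, 4], c(-4, 0, 0), tolerance = 1e-9)
  # random small affines: contract holds to 1e-6 (exceeds it comfortably)
  set.seed(5)
  affs <- lapply(1:6, function(i) {
    M <- diag(4)
    M[1:3, 1:3] <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
    M[1:3, 4] <- rnorm(3, 0, 5)
    affine_transform(M)
  })
  out3 <- midspace_transforms(affs)
  logs <- lapply(out3, function(a) affine_logm(a$matrix))
  expect_lt(norm(Reduce(`+`, logs) / length(logs), "F"), 1e-6)
  # transforms with a negative real eigenvalue have no real log
  bad <- affine_transform(diag(c(-1, -1, 1, 1)))
  expect_error(midspace_transforms(list(bad, affine_identity())), "subject 1")
})

test_that("affine log and exp are mutual inverses on small transforms", {
  set.seed(6)
  M <- diag(4)
  M[1:3, 1:3] <- diag(3) + matrix(rnorm(9, 0, 0.08), 3, 3)
  M[1:3, 4] <- rnorm(3, 0, 3)
  expect_equal(affine_expm(affine_logm(M)), M, tolerance = 1e-10)
  expect_equal(affine_logm(diag(4)), matrix(0, 4, 4), tolerance = 1e-12)
})

test_that("affine registration recovers identity, translations and scale", {
  p <- small_phantom_params(noise_sd = list(t1 = 5, flair = 5, dti = 0))
  can <- make_canonical_anatomy(p)
  # identical images: identity within 0.1 mm / 0.1 degree
  A0 <- affine_register(can$t1, can$t1, dof = "rigid6", maxit = 150)
  expect_lt(max(abs(A0$matrix[1:3, 4])), 0.1)
  expect_lt(max(abs(A0$matrix[1:3, 1:3] - diag(3))), 0.1 * pi / 180 + 1e-6)
  # known translation recovered within 0.5 mm (A estimates the inverse map)
  tr <- affine_transform(rbind(c(1, 0, 0, 4), c(0, 1, 0, -2),
                               c(0, 0, 1, 3), c(0, 0, 0, 1)))
  mov <- resample_scalar(can$t1, tr, order = 3)
  A <- affine_register(mov, can$t1, dof = "rigid6", maxit = 300)
  expect_lt(max(abs((A$matrix %*% tr$matrix)[1:3, 4])), 0.5)
  # known 5% scale recovered within 0.01 with 12 DOF
  sc <- affine_transform(diag(c(1.05, 1.05, 1.05, 1)))
  mov2 <- resample_scalar(can$t1, sc, order = 3)
  A2 <- affine_register(mov2, can$t1, dof = "affine12", maxit = 300)
  expect_equal(diag(A2$matrix)[1:3], rep(1 / 1.05, 3), tolerance = 0.01)
})

test_that("weight mask construction forces ratio 8 and whole-volume mean 1", {
  g <- tiny_grid(10, 1)
  # toy: 250 of 1000 voxels inside
  v <- array(0, g$shape); v[1:5, 1:5, 1:10] <- 1
  wm <- make_weight_mask(weight_image(g, v))
  expect_equal(mean(wm$values), 1, tolerance = 1e-12)
  expect_equal(max(wm$values) / min(wm$values), 8, tolerance = 1e-12)
  expect_equal(max(wm$values), 8 / 2.75, tolerance = 1e-12)   # 25% inside
  expect_equal(min(wm$values), 1 / 2.75, tolerance = 1e-12)
  # all-inside mask collapses to uniform 1
  wall <- make_weight_mask(weight_image(g, array(1, g$shape)))
  expect_equal(range(wall$values), c(1, 1))
  expect_error(make_weight_mask(weight_image(g, array(0, g$shape))), "empty")
  # property over random soft masks
  set.seed(7)
  for (i in 1:20) {
    soft <- array(runif(prod(g$shape)), g$shape)
    w <- make_weight_mask(weight_image(g, soft))
    expect_equal(mean(w$values), 1, tolerance = 1e-12)
    ratio <- max(w$values) / min(w$values)
    expect_true(abs(ratio - 8) < 1e-9 || abs(ratio - 1) < 1e-9)
  }
})

test_that("DTI soft mask shrinks a cube by two voxels per face", {
  g <- tiny_grid(16, 1)
  v <- array(0, g$shape); v[4:13, 4:13, 4:13] <- 1
  out <- make_dti_soft_mask(scalar_image(g, v))
  expected <- array(0, g$shape); expected[6:11, 6:11, 6:11] <- 1
  expect_equal(out$values, expected)
  # isolated voxel disappears; empty mask stays empty
  v1 <- array(0, g$shape); v1[8, 8, 8] <- 1
  expect_equal(sum(make_dti_soft_mask(scalar_image(g, v1))$values), 0)
  expect_equal(sum(make_dti_soft_mask(scalar_image(g, array(0, g$shape)))$values), 0)
  # unnormalised (literal box-sum) variant keeps the full cube interior
  out2 <- make_dti_soft_mask(scalar_image(g, v), normalised = FALSE)
  expect_gt(sum(out2$values), sum(out$values))
})

test_that("scalp clamping is monotone, bounded and inert when not needed", {
  g <- tiny_grid(8, 1)
  set.seed(8)
  n <- prod(g$shape)
  brain <- array(0, g$shape); brain[3:6, 3:6, 3:6] <- 1
  v <- array(runif(n, 0, 100), g$shape)
  out0 <- clamp_scalp_intensities(scalar_image(g, pmin(v, 50)), scalar_image(g, brain),
                                  percentile = 99, softness = 0.2)
  # values all far below any high tail: at most the top percent changes
  expect_lt(mean(out0$values != pmin(v, 50)), 0.02)
  # add a bright scalp tail
  v2 <- v; v2[brain == 0][1:40] <- seq(500, 900, length.out = 40)
  img <- scalar_image(g, v2)
  out <- clamp_scalp_intensities(img, scalar_image(g, brain), 99, 0.2)
  outside <- brain == 0
  ov_in <- v2[outside]; ov_out <- out$values[outside]
  expect_true(all(diff(ov_out[order(ov_in)]) >= -1e-9))  # order preserved
  thr <- quantile(ov_in, 0.99, names = FALSE)
  expect_lte(max(ov_out), thr + 0.2 * (max(ov_in) - thr) + 1e-9)
  expect_equal(out$values[brain == 1], v2[brain == 1])   # in-brain untouched
})

test_that("affine template of identical subjects reproduces the subject", {
  p <- still_phantom_params()
  subs <- lapply(1:3, function(i) {
    s <- make_subject(p, p$reference_age, subject_seed = i)
    s$id <- sprintf("sub-%03d", i)
    s
  })
  cohort <- structure(list(subjects = subs, params = p), class = "SyntheticCohort")
  res <- build_affine_template(cohort, seed_subject = 1L, maxit = 120)
  expect_lt(rel_rms(res$template$t1$values, subs[[1]]$t1$values), 1e-3)
  logs <- lapply(res$affines, function(a) affine_logm(a$matrix))
  expect_lt(norm(Reduce(`+`, logs) / length(logs), "F"), 1e-6)
})

test_that("affine template centres a symmetric two-subject cohort", {
  p <- still_phantom_params()
  can <- make_canonical_anatomy(p)
  tshift <- function(t) affine_transform(rbind(cbind(diag(3), t), c(0, 0, 0, 1)))
  mk <- function(t, id) {
    s <- can
    s$t1 <- resample_scalar(can$t1, tshift(t), 3)
    s$flair <- resample_scalar(can$flair, tshift(t), 3)
    s$dti <- resample_tensor(can$dti, tshift(t))
    s$brain_mask <- scalar_image(can$t1$grid,
      round(resample_scalar(can$brain_mask, tshift(t), 1)$values))
    s$id <- id
    s
  }
  cohort <- structure(list(subjects = list(mk(c(6, 0, 0), "a"), mk(c(-6, 0, 0), "b")),
                           params = p), class = "SyntheticCohort")
  res <- build_affine_template(cohort, seed_subject = 1L, maxit = 250)
  com_t <- omtemplate:::com_world(res$template$t1)
  com_c <- omtemplate:::com_world(can$t1)
  expect_lt(sqrt(sum((com_t - com_c)^2)), 0.5 * p$voxel_size)
})

test_that("the affine template is independent of the seed subject up to alignment", {
  p <- small_phantom_params(subject_warp_amplitude = 1.5, seed = 23,
                            noise_sd = list(t1 = 5, flair = 5, dti = 0))
  cohort <- make_cohort(p, 3, 50, 55, seed = 23)
  r1 <- build_affine_template(cohort, seed_subject = 1L, maxit = 150)
  r2 <- build_affine_template(cohort, seed_subject = 2L, maxit = 150)
  # align template 2 onto template 1 and compare normalised intensities
  A <- affine_register(r2$template$t1, r1$template$t1, dof = "affine12",
                       maxit = 300)
  t2on1 <- resample_scalar(r2$template$t1, A, order = 3)
  n1 <- normalize_intensity(r1$template$t1, 10)
  n2 <- normalize_intensity(t2on1, 10)
  mask <- n1$values > 100 & n2$values > 100
  err <- sqrt(mean((n1$values[mask] - n2$values[mask])^2)) /
    sqrt(mean(n1$values[mask]^2))
  expect_lte(err, 0.02)
})
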