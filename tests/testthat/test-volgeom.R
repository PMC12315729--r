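test_that("warp composition handles identity, translations and inverses", {
  g <- tiny_grid()
  w <- sinusoid_field(g)
  # identity outer leaves the field unchanged
  expect_equal(compose_warps(zero_field(g), w)$disp, w$disp, tolerance = 1e-12)
  # translations commute and add
  t1 <- uniform_translation_field(g, c(1, -2, 0.5))
  t2 <- uniform_translation_field(g, c(3, 1, -1))
  h <- compose_warps(t1, t2)
  expect_equal(matrix(h$disp, ncol = 3)[1, ], c(4, -1, -0.5), tolerance = 1e-12)
  # inversion residual: compose(invert(w), w) ~ 0 (<= 0.05 voxel)
  wi <- invert_warp(w, tol = 0.005, max_iter = 100)
  res <- compose_warps(w, wi)
  expect_lt(max(field_mag(res)), 0.05 * 2)
})

test_that("compose_affine_warp is exact and invert_warp handles easy cases", {
  g <- tiny_grid()
  w <- sinusoid_field(g)
  expect_equal(compose_affine_warp(affine_identity(), w)$disp, w$disp,
               tolerance = 1e-14)
  tr <- affine_transform(rbind(c(1, 0, 0, 2), c(0, 1, 0, -1),
                               c(0, 0, 1, 4), c(0, 0, 0, 1)), "rigid6")
  h <- compose_affine_warp(tr, zero_field(g))
  expect_equal(matrix(h$disp, ncol = 3)[5, ], c(2, -1, 4), tolerance = 1e-14)
  # scaling by 2 about the origin: displacement x at point x
  sc <- affine_transform(diag(c(2, 2, 2, 1)))
  h2 <- compose_affine_warp(sc, zero_field(g))
  pts <- omtemplate:::grid_world_coords(g)
  expect_equal(matrix(h2$disp, ncol = 3), pts, tolerance = 1e-12)
  # translation inverts to its negation; zero stays zero
  tf <- uniform_translation_field(g, c(2, 0, -1))
  expect_equal(matrix(invert_warp(tf)$disp, ncol = 3)[1, ], c(-2, 0, 1),
               tolerance = 1e-9)
  expect_equal(invert_warp(zero_field(g))$disp, zero_field(g)$disp)
  expect_error(invert_warp(sinusoid_field(g, amp = 50), tol = 1e-6, max_iter = 3),
               "did not converge")
})

test_that("mean_warp averages, errors on empty input, is permutation invariant", {
  g <- tiny_grid(8)
  w <- sinusoid_field(g)
  neg <- scale_warp(w, -1)
  expect_equal(max(abs(mean_warp(list(w, neg))$disp)), 0)
  expect_equal(mean_warp(list(w, w, w))$disp, w$disp)
  t1 <- uniform_translation_field(g, c(1, 0, 0))
  t3 <- uniform_translation_field(g, c(3, 0, 0))
  expect_equal(matrix(mean_warp(list(t1, t3))$disp, ncol = 3)[1, ], c(2, 0, 0))
  expect_error(mean_warp(list()), "empty")
  set.seed(1)
  ws <- lapply(1:4, function(i) displacement_field(g, matrix(rnorm(prod(g$shape) * 3), ncol = 3)))
  # permutation invariance (exact up to IEEE addition order)
  expect_equal(mean_warp(ws)$disp, mean_warp(rev(ws))$disp, tolerance = 1e-14)
})

test_that("jacobian determinant matches closed forms and the chain rule", {
  g <- tiny_grid()
  expect_equal(jacobian_determinant_map(zero_field(g))$values,
               array(1, g$shape), tolerance = 1e-14)
  sc <- affine_to_field(affine_transform(diag(c(1.1, 1.1, 1.1, 1))), g)
  expect_equal(range(jacobian_determinant_map(sc)$values),
               rep(1.1^3, 2), tolerance = 1e-9)
  # general affine: det of linear part everywhere
  L <- rbind(c(1.1, 0.05, 0), c(-0.02, 0.95, 0.03), c(0, 0.04, 1.02))
  M <- diag(4); M[1:3, 1:3] <- L; M[1:3, 4] <- c(1, -2, 0.5)
  f <- affine_to_field(affine_transform(M), g)
  jd <- jacobian_determinant_map(f)$values
  expect_equal(max(abs(jd - det(L))), 0, tolerance = 1e-6)
  # chain rule within 2% on interior voxels for smooth fields
  w1 <- sinusoid_field(g, 1.2)
  w2 <- sinusoid_field(g, 0.8)
  comp <- compose_warps(w1, w2)
  j_comp <- jacobian_determinant_map(comp)$values
  j_inner <- jacobian_determinant_map(w2)$values
  jmap_outer <- jacobian_determinant_map(w1)
  pts <- omtemplate:::mapped_world_points(w2)
  vox <- omtemplate:::world_to_voxel_points(g, pts)
  j_outer_at <- omtemplate:::interp_at_voxels(jmap_outer$values, vox, 1, "clamp")$values
  interior <- array(FALSE, g$shape); interior[4:13, 4:13, 4:13] <- TRUE
  ratio <- (j_comp / (array(j_outer_at, g$shape) * j_inner))[interior]
  expect_lt(max(abs(ratio - 1)), 0.02)
})

test_that("scalar resampling respects identity, shifts and smooth round trips", {
  g <- tiny_grid()
  pts <- omtemplate:::grid_world_coords(g)
  v <- array(sin(pts[, 1] / 6) * cos(pts[, 2] / 7) + 0.3 * sin(pts[, 3] / 9),
             g$shape)
  img <- scalar_image(g, v)
  out0 <- resample_scalar(img, zero_field(g), order = 0)
  expect_identical(out0$values, img$values)
  out1 <- resample_scalar(img, zero_field(g), order = 1)
  expect_equal(out1$values, img$values, tolerance = 1e-12)
  # integer-voxel translation shifts the image, zero-filled
  tr <- affine_transform(rbind(c(1, 0, 0, 2), c(0, 1, 0, 0),
                               c(0, 0, 1, 0), c(0, 0, 0, 1)))
  out <- resample_scalar(img, tr, order = 1)
  expect_equal(out$values[1:14, , ], img$values[2:15, , ], tolerance = 1e-12)
  expect_true(all(out$values[16, , ] == 0))
  # half-voxel round trip with cubic interpolation on a smooth image
  half <- function(s) affine_transform(rbind(c(1, 0, 0, s), c(0, 1, 0, 0),
                                             c(0, 0, 1, 0), c(0, 0, 0, 1)))
  rt <- resample_scalar(resample_scalar(img, half(1), 3), half(-1), 3)
  interior <- array(FALSE, g$shape); interior[3:14, 3:14, 3:14] <- TRUE
  expect_lt(max(abs(rt$values[interior] - img$values[interior])), 1e-3)
  expect_error(resample_scalar(img, zero_field(g), order = 2), "order")
})

test_that("tensor resampling preserves identity, rotates by PPD, ignores translation", {
  g <- tiny_grid(9, 1)
  n <- prod(g$shape)
  tens <- matrix(0, n, 6)
  tens[, 1] <- 1.5e-3; tens[, 4] <- 0.3e-3; tens[, 6] <- 0.3e-3
  ti <- tensor_image(g, tens)
  out <- resample_tensor(ti, zero_field(g))
  expect_equal(out$tensors, ti$tensors, tolerance = 1e-12)
  # active rotation by +90 deg about z: map is the inverse rotation
  th <- -pi / 2
  Rm <- diag(4); Rm[1:2, 1:2] <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  rot <- resample_tensor(ti, affine_transform(Rm, "rigid6"))
  centre <- matrix(rot$tensors[5, 5, 5, ], 1)
  expect_equal(as.numeric(centre), c(0.3e-3, 0, 0, 1.5e-3, 0, 0.3e-3),
               tolerance = 1e-9) # principal axis now along y
  # eigenvalues unchanged under rotation
  ev <- eig_sym3_batch(centre)$values
  expect_equal(as.numeric(ev), c(1.5e-3, 0.3e-3, 0.3e-3), tolerance = 1e-9)
  # pure translation leaves orientations unchanged
  tr <- affine_transform(rbind(c(1, 0, 0, 1), c(0, 1, 0, 0),
                               c(0, 0, 1, 0), c(0, 0, 0, 1)), "rigid6")
  sh <- resample_tensor(ti, tr)
  inb <- which(as.logical(sh$valid))
  expect_equal(tensor_matrix(sh)[inb, ],
               matrix(rep(c(1.5e-3, 0, 0, 0.3e-3, 0, 0.3e-3), length(inb)),
                      ncol = 6, byrow = TRUE), tolerance = 1e-9)
})

test_that("rigid-rotation equivariance of tensor resampling holds to 1e-5", {
  # voxel centres map exactly to voxel centres under this 90 degree rotation
  g <- tiny_grid(9, 1)
  set.seed(7)
  R1 <- random_rotation()
  D <- R1 %*% diag(c(1.7, 0.5, 0.2) * 1e-3) %*% t(R1)
  tens <- matrix(rep(tensor6_from_matrix(D), each = prod(g$shape)), ncol = 6)
  ti <- tensor_image(g, tens)
  th <- -pi / 2
  Rm <- diag(4); Rm[1:2, 1:2] <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  out <- resample_tensor(ti, affine_transform(Rm, "rigid6"))
  Rz <- t(Rm[1:3, 1:3])          # the active rotation
  expected <- Rz %*% D %*% t(Rz)
  got <- matrix_from_tensor6(out$tensors[5, 5, 5, ])
  expect_equal(got, expected, tolerance = 1e-5)
})

test_that("log-Euclidean mean matches closed forms and flags invalid input", {
  D <- diag(c(2, 1, 0.5))
  expect_equal(log_euclidean_mean(list(D, D, D)), D, tolerance = 1e-12,
               ignore_attr = TRUE)
  m <- log_euclidean_mean(list(diag(c(2, 3, 4)), diag(c(8, 3, 1))))
  expect_equal(diag(m), sqrt(c(16, 9, 4)), tolerance = 1e-12)
  expect_equal(m[upper.tri(m)], rep(0, 3), tolerance = 1e-12)
  # no valid tensors -> zero with valid = FALSE
  z <- log_euclidean_mean(list(matrix(0, 3, 3)))
  expect_false(attr(z, "valid"))
  expect_equal(z, matrix(0, 3, 3), ignore_attr = TRUE)
  # validity mask excludes entries
  m2 <- log_euclidean_mean(list(diag(3), diag(c(100, 100, 100))),
                           valid = c(TRUE, FALSE))
  expect_equal(m2, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Euclidean tensor averaging swells determinants; log-Euclidean does not", {
  # the provable anti-swelling property: det(Euclidean mean) >= det(LE mean)
  # (= geometric mean of determinants), for all positive-definite pairs
  set.seed(11)
  for (i in 1:200) {
    R1 <- random_rotation(); R2 <- random_rotation()
    D1 <- R1 %*% diag(runif(3, 0.2, 2)) %*% t(R1)
    D2 <- R2 %*% diag(runif(3, 0.2, 2)) %*% t(R2)
    le <- log_euclidean_mean(list(D1, D2))
    expect_gte(det((D1 + D2) / 2), det(le) - 1e-10)
    expect_equal(det(le), sqrt(det(D1) * det(D2)), tolerance = 1e-8)
  }
})

test_that("fa_map matches the closed-form eigenvalue formula", {
  g <- tiny_grid(4, 1)
  n <- prod(g$shape)
  tens <- matrix(0, n, 6)
  tens[1, c(1, 4, 6)] <- 2e-3                      # isotropic
  tens[2, 1] <- 1e-3                               # rank one
  tens[3, c(1, 4, 6)] <- c(3, 1, 1) * 1e-3         # prolate
  set.seed(3)
  R1 <- random_rotation()
  D <- R1 %*% diag(c(1.9, 0.6, 0.3) * 1e-3) %*% t(R1)
  tens[4, ] <- tensor6_from_matrix(D)
  ti <- tensor_image(g, tens)
  fa <- fa_map(ti)$values
  expect_equal(fa[1], 0, tolerance = 1e-12)
  expect_equal(fa[2], 1, tolerance = 1e-9)
  fa_oracle <- function(l) {
    lb <- mean(l); sqrt(3 / 2) * sqrt(sum((l - lb)^2) / sum(l^2))
  }
  expect_equal(fa[3], fa_oracle(c(3, 1, 1) * 1e-3), tolerance = 1e-10)
  expect_equal(fa[4], fa_oracle(c(1.9, 0.6, 0.3) * 1e-3), tolerance = 1e-8)
  expect_equal(fa[5], 0) # zero tensor is invalid -> 0
})

test_that("voxelwise median and valid-voxel mean behave as specified", {
  g <- tiny_grid(4, 1)
  mk <- function(v) scalar_image(g, array(v, g$shape))
  med <- voxelwise_median(list(mk(1), mk(2), mk(100)))
  expect_equal(med$values[1], 2)
  expect_equal(voxelwise_median(list(mk(7), mk(7)))$values, array(7, g$shape))
  expect_error(voxelwise_median(list()), "empty")
  mv <- voxelwise_mean_valid(list(mk(10), mk(99)),
                             list(array(TRUE, g$shape), array(FALSE, g$shape)))
  expect_equal(mv$values[1], 10)
  mv2 <- voxelwise_mean_valid(list(mk(10), mk(99)),
                              list(array(FALSE, g$shape), array(FALSE, g$shape)))
  expect_equal(mv2$values[1], 0)
})

test_that("type constructors enforce their invariants", {
  expect_error(image_grid(c(4, 4, 4), matrix(0, 4, 4)), "invertible")
  expect_error(scalar_image(tiny_grid(4), rep(NA_real_, 64)), "finite")
  expect_error(weight_image(tiny_grid(4), rep(-1, 64)), "nonnegative")
  expect_error(affine_transform(diag(c(2, 1, 1, 1)), "rigid6"), "orthogonal")
  ok <- affine_transform(diag(4), "rigid6")
  expect_s3_class(affine_inverse(ok), "AffineTransform")
  # tensor validity: non-positive-definite voxels are auto-invalid
  g <- tiny_grid(3, 1)
  tens <- matrix(0, 27, 6)
  tens[1, c(1, 4, 6)] <- c(-1, -1, -1)
  tens[2, c(1, 4, 6)] <- 1
  ti <- tensor_image(g, tens)
  expect_false(ti$valid[1])
  expect_true(ti$valid[2])
})
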