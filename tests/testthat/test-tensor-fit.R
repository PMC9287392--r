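# Log-linear tensor estimation, eigendecomposition, scalar maps and the
# residual bootstrap.

test_that("eigensystem matches characteristic-polynomial roots and rebuilds D", {
  es <- eigensystem(diag(c(3, 2, 1)))
  expect_equal(es$values, c(3, 2, 1))
  expect_equal(abs(es$vectors), diag(3), tolerance = 1e-12)

  set.seed(1)
  for (i in 1:50) {
    cf <- random_tensor()
    m <- ondti:::as_tensor_matrix(cf)
    es <- eigensystem(cf)
    # oracle: polynomial roots
    expect_equal(es$values, charpoly_eigenvalues(m), tolerance = 1e-12)
    # reconstruction
    rec <- es$vectors %*% diag(es$values) %*% t(es$vectors)
    expect_lt(max(abs(rec - m)), 1e-12)
    # orthonormal, sign convention
    expect_equal(crossprod(es$vectors), diag(3), tolerance = 1e-12)
    for (j in 1:3)
      expect_gt(es$vectors[which.max(abs(es$vectors[, j])), j], 0)
  }

  # axial degeneracy: e2/e3 span the correct plane (projector comparison)
  t1 <- c(1, 0, 0)
  m <- 0.5 * diag(3) + (2 - 0.5) * tcrossprod(t1)
  es <- eigensystem(m)
  P23 <- tcrossprod(es$vectors[, 2]) + tcrossprod(es$vectors[, 3])
  expect_equal(P23, diag(3) - tcrossprod(t1), tolerance = 1e-12)

  expect_error(eigensystem(c(1, NA, 1, 0, 0, 0)), "finite")
})

test_that("noiseless fits recover the ground-truth tensor to machine precision", {
  ph <- noiseless_phantom()
  tf <- fit_tensor_lls(merge_b0_pairs(ph$dwi))
  truth <- ph$truth
  expect_lt(max(abs(tf$coef - truth$coef)), 1e-9)
  # isotropic voxels: all three eigenvalues equal MD
  it <- attr(truth, "in_tube")
  rows_bg <- tf$row_of_voxel[!it]
  expect_lt(max(abs(tf$evals[rows_bg, ] - 3.0)), 1e-9)
})

test_that("fit preconditions and exclusion rules are enforced", {
  ph <- noiseless_phantom()
  ds <- merge_b0_pairs(ph$dwi)
  # rank-deficient: all directions collinear
  g <- ds$gradients
  bad <- gradient_table(g$bvals, matrix(rep(c(1, 0, 0), length(g)),
                                        ncol = 3, byrow = TRUE) *
                          (g$bvals > 0))
  ds_bad <- ds; ds_bad$gradients <- bad
  expect_error(fit_tensor_lls(ds_bad), "collinear")

  # fewer than one b0 / six DWI
  sub <- dwi_dataset(ds$signal[, , , 1:5],
                     ds$affine,
                     gradient_table(g$bvals[1:5], g$bvecs[1:5, ],
                                    g$phase_dir[1:5]))
  expect_error(fit_tensor_lls(sub), "at least one b0")

  # a voxel with too many nonpositive signals is dropped from the mask
  ds2 <- ds
  ds2$signal[1, 1, 1, ] <- 0
  mask <- array(FALSE, dim(ds2$signal)[1:3]); mask[1:2, 1, 1] <- TRUE
  expect_warning(tf2 <- fit_tensor_lls(ds2, mask), "excluded")
  expect_false(tf2$mask[1, 1, 1])
  expect_true(tf2$mask[2, 1, 1])
})

test_that("fitted tensors are invariant to global signal scaling", {
  ph <- noisy_fitted()$ph
  ds <- merge_b0_pairs(ph$dwi)
  mask <- array(FALSE, dim(ds$signal)[1:3]); mask[10:14, 10:14, 8] <- TRUE
  tf1 <- fit_tensor_lls(ds, mask)
  ds2 <- ds; ds2$signal <- ds$signal * 3.7
  tf2 <- fit_tensor_lls(ds2, mask)
  expect_equal(tf1$coef, tf2$coef, tolerance = 1e-10)
  expect_equal(tf2$s0 / tf1$s0, rep(3.7, length(tf1$s0)), tolerance = 1e-10)
})

test_that("rotating gradients and phantom together leaves the maps unchanged", {
  # rotate the straight tube from +y to +x and rotate the gradient table the
  # same way: FA/MD/AD/RD must agree voxel-for-voxel (after axis swap)
  theta <- pi / 2
  R <- matrix(c(cos(theta), sin(theta), 0,
                -sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3)   # maps +y to +x... columns act on (x,y,z)
  gt <- tiny_gradients(n = 16)
  sp_y <- phantom_spec(grid_shape = c(20, 20, 14),
                       centerline_ctrl_points =
                         cbind(rep(19, 2), 19 + c(-11, 11), rep(13, 2)),
                       snr = Inf)
  sp_x <- phantom_spec(grid_shape = c(20, 20, 14),
                       centerline_ctrl_points =
                         cbind(19 + c(-11, 11), rep(19, 2), rep(13, 2)),
                       snr = Inf)
  truth_y <- ground_truth_tensors(sp_y)
  truth_x <- ground_truth_tensors(sp_x)
  gt_rot <- gradient_table(gt$bvals, t(R %*% t(gt$bvecs)), gt$phase_dir)

  maps_y <- scalar_maps(fit_tensor_lls(merge_b0_pairs(
    simulate_signal(truth_y, gt, snr = Inf))))
  maps_x <- scalar_maps(fit_tensor_lls(merge_b0_pairs(
    simulate_signal(truth_x, gt_rot, snr = Inf))))
  # voxel (i,j,k) of the y-tube corresponds to (j,i,k) of the x-tube
  perm <- aperm(maps_x$fa, c(2, 1, 3))
  expect_equal(maps_y$fa, perm, tolerance = 1e-6)
  perm_md <- aperm(maps_x$md, c(2, 1, 3))
  expect_equal(maps_y$md, perm_md, tolerance = 1e-6)
})

test_that("scalar maps satisfy the definitional identities", {
  maps <- noisy_fitted()$maps
  msk <- !is.na(maps$fa)
  expect_true(all(maps$fa[msk] >= 0 & maps$fa[msk] <= 1))
  expect_lt(max(abs(maps$md[msk] - (maps$ad[msk] + 2 * maps$rd[msk]) / 3)),
            1e-10)

  # canonical cases
  expect_equal(fa_from_evals(1, 1, 1), 0)
  expect_equal(fa_from_evals(1, 0, 0), 1)
  expect_equal((1.123 + 2 * 0.920) / 3, 0.988, tolerance = 5e-4)

  # negative eigenvalues clamp for FA only; MD identity untouched
  tfn <- tensor_field(matrix(c(1, 1, -0.2, 0, 0, 0), 1), {
    m <- array(FALSE, c(1, 1, 1)); m[1] <- TRUE; m
  }, diag(4))
  mn <- scalar_maps(tfn)
  expect_lte(mn$fa[1], 1)
  expect_equal(mn$md[1], (mn$ad[1] + 2 * mn$rd[1]) / 3)
  expect_equal(attr(mn, "n_clamped"), 1L)
})

test_that("fit agrees with an independent nonlinear least-squares oracle", {
  # nls on the exponential signal model, random noiseless voxels
  gt <- tiny_gradients(n = 20)
  X <- ondti:::tensor_design(gt)
  set.seed(42)
  for (i in 1:20) {
    cf <- random_tensor()
    q <- apply(gt$bvecs, 1, function(g)
      g %*% ondti:::as_tensor_matrix(cf) %*% g)
    s <- 500 * exp(-gt$bvals * 1e-3 * q)
    sig <- array(rep(s, each = 1), c(1, 1, 1, length(gt)))
    ds <- dwi_dataset(sig, diag(4), gt)
    tf <- fit_tensor_lls(ds)
    # oracle: Gauss-Newton on the nonlinear signal model S = exp(X theta)
    th <- c(log(500) * 1.05, cf * 0.9)
    for (k in 1:60) {
      f <- as.vector(exp(X %*% th))
      J <- f * X
      th <- th + solve(crossprod(J), crossprod(J, s - f))
    }
    expect_lt(max(abs(tf$coef[1, ] - th[2:7])), 1e-6)
    expect_lt(max(abs(tf$coef[1, ] - cf)), 1e-6)
  }
})

test_that("residual bootstrap is seeded, sized and noise-responsive", {
  ph <- noiseless_phantom()
  ds <- merge_b0_pairs(ph$dwi)
  mask <- array(FALSE, dim(ds$signal)[1:3])
  mask[11:13, 11:13, 8] <- TRUE

  # noiseless data: zero residuals, zero bootstrap SD
  b0 <- bootstrap_tensor(ds, mask, n_boot = 50, seed = 1)
  expect_lt(max(b0$sd$fa[mask]), 1e-8)
  expect_lt(max(b0$sd$md[mask]), 1e-8)
  expect_equal(b0$n_boot, 50L)

  expect_error(bootstrap_tensor(ds, mask, n_boot = 1), "at least 2")

  # noisy data: seeded reproducibility and monotone response to noise level
  sp <- small_spec(seed = 5)
  noisy1 <- make_phantom(sp)
  sp2 <- small_spec(snr = 10, seed = 5)
  noisy2 <- make_phantom(sp2)
  m1 <- bootstrap_tensor(merge_b0_pairs(noisy1$dwi), mask, n_boot = 60,
                         seed = 2)
  m1b <- bootstrap_tensor(merge_b0_pairs(noisy1$dwi), mask, n_boot = 60,
                          seed = 2)
  m2 <- bootstrap_tensor(merge_b0_pairs(noisy2$dwi), mask, n_boot = 60,
                         seed = 2)
  expect_identical(m1$sd$fa, m1b$sd$fa)
  expect_gt(mean(m2$sd$fa[mask]), mean(m1$sd$fa[mask]))
})

test_that("scalar maps write and re-read as NIfTI with the input affine", {
  maps <- noisy_fitted()$maps
  td <- withr::local_tempdir()
  paths <- write_scalar_maps(maps, td)
  img <- RNifti::readNifti(paths["fa"])
  back <- as.array(img)
  ref <- maps$fa; ref[is.na(ref)] <- 0
  expect_equal(as.vector(back), as.vector(ref), tolerance = 1e-6)
  expect_equal(unclass(RNifti::xform(img))[1:3, 1:3], maps$affine[1:3, 1:3],
               tolerance = 1e-6, ignore_attr = TRUE)
})
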