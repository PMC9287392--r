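# Diffusivities are stored and reported on the printed clinical scale
# (numerically 10^-3 mm^2/s); the conversion to mm^2/s happens only where
# b.D must be dimensionless (signal model / design matrix).
DIFF_UNIT <- 1e-3

#' Symmetric eigendecomposition of a 3x3 diffusion tensor
#'
#' Eigenvalues are returned in descending order; eigenvectors are orthonormal
#' columns with the sign fixed so that the largest-magnitude component of each
#' vector is positive.
#'
#' @param tensor either a symmetric 3x3 matrix or a length-6 vector of unique
#'   components (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @return list with \code{values} (descending) and \code{vectors}
#'   (3x3, column i paired with value i).
#' @export
eigensystem <- function(tensor) {
  m <- as_tensor_matrix(tensor)
  if (any(!is.finite(m))) stop("non-finite tensor components")
  e <- eigen(m, symmetric = TRUE)   # eigen() already sorts descending
  v <- e$vectors
  for (i in 1:3) {
    j <- which.max(abs(v[, i]))
    if (v[j, i] < 0) v[, i] <- -v[, i]
  }
  list(values = e$values, vectors = v)
}

as_tensor_matrix <- function(tensor) {
  if (is.matrix(tensor)) {
    stopifnot(all(dim(tensor) == c(3L, 3L)))
    return((tensor + t(tensor)) / 2)
  }
  stopifnot(length(tensor) == 6L)
  matrix(c(tensor[1], tensor[4], tensor[5],
           tensor[4], tensor[2], tensor[6],
           tensor[5], tensor[6], tensor[3]), 3, 3)
}

#' Per-voxel tensor field
#'
#' Container for the six unique tensor components over a voxel mask, with the
#' eigensystem precomputed per voxel.  Component columns are ordered
#' Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, on the printed diffusivity scale.
#'
#' @param coef n_masked x 6 component matrix.
#' @param mask logical 3D array selecting the n_masked voxels
#'   (column-major order matches the rows of \code{coef}).
#' @param affine 4x4 voxel-to-mm matrix.
#' @param s0 optional per-voxel baseline signal estimate.
#' @param evals,evecs optional precomputed eigensystem (n x 3 descending
#'   values; n x 3 x 3 vectors, \code{evecs[i, , j]} paired with
#'   \code{evals[i, j]}), e.g. when the field is constructed analytically.
#' @return an object of class \code{tensor_field}.
#' @export
tensor_field <- function(coef, mask, affine, s0 = NULL,
                         evals = NULL, evecs = NULL) {
  coef <- as.matrix(coef)
  stopifnot(ncol(coef) == 6L, is.logical(mask), length(dim(mask)) == 3L,
            sum(mask) == nrow(coef))
  if (any(!is.finite(coef))) stop("every masked voxel must carry a finite tensor")
  n <- nrow(coef)
  if (is.null(evals) || is.null(evecs)) {
    evals <- matrix(NA_real_, n, 3)
    evecs <- array(NA_real_, c(n, 3, 3))
    for (i in seq_len(n)) {
      es <- eigensystem(coef[i, ])
      evals[i, ] <- es$values
      evecs[i, , ] <- es$vectors
    }
  }
  row_of <- array(NA_integer_, dim(mask))
  row_of[mask] <- seq_len(n)
  structure(list(coef = coef, mask = mask, dim = dim(mask), affine = affine,
                 s0 = s0, evals = evals, evecs = evecs, row_of_voxel = row_of),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(x$dim, collapse = "x"), " grid, ",
      nrow(x$coef), " masked voxels\n", sep = "")
  invisible(x)
}

# design matrix of the log-linear tensor model:
# ln S_i = ln S0 - b_i * g_i' D g_i   (D on the printed scale, hence b*1e-3)
tensor_design <- function(gradients) {
  b <- gradients$bvals * DIFF_UNIT
  g <- gradients$bvecs
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Solves, per masked voxel, the ordinary least-squares problem
#' \code{ln S_i = ln S0 - b_i g_i' D g_i} for the six tensor components plus
#' \code{ln S0} on the log-signal design matrix.  Non-positive signal values
#' are dropped measurement-wise; a voxel retaining fewer than 7 measurements
#' is removed from the mask (the count is reported as an attribute).
#'
#' @param ds a [dwi_dataset()] with at least one b0 and six non-collinear
#'   diffusion directions.
#' @param mask logical 3D array of voxels to fit; default all voxels.
#' @return a [tensor_field()]; attribute \code{n_dropped_voxels} counts voxels
#'   excluded for insufficient usable measurements.
#' @export
fit_tensor_lls <- function(ds, mask = NULL) {
  stopifnot(inherits(ds, "dwi_dataset"))
  g <- ds$gradients
  if (sum(g$bvals == 0) < 1L || sum(g$bvals > 0) < 6L)
    stop("need at least one b0 and six diffusion-weighted volumes")
  X <- tensor_design(g)
  if (qr(X)$rank < 7L)
    stop("rank-deficient gradient design: directions are collinear")
  d <- dim(ds$signal)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  stopifnot(all(dim(mask) == d[1:3]))

  nvol <- d[4]
  sig <- matrix(ds$signal, ncol = nvol)[as.vector(mask), , drop = FALSE]
  n <- nrow(sig)
  coefs <- matrix(NA_real_, n, 7)
  ok_all <- rowSums(sig > 0) == nvol
  if (any(ok_all)) {
    XtXinvXt <- solve(crossprod(X), t(X))
    coefs[ok_all, ] <- t(XtXinvXt %*% t(log(sig[ok_all, , drop = FALSE])))
  }
  dropped <- 0L
  for (i in which(!ok_all)) {
    keep <- sig[i, ] > 0
    if (sum(keep) < 7L) { dropped <- dropped + 1L; next }
    Xi <- X[keep, , drop = FALSE]
    if (qr(Xi)$rank < 7L) { dropped <- dropped + 1L; next }
    coefs[i, ] <- solve(crossprod(Xi), crossprod(Xi, log(sig[i, keep])))
  }
  good <- !is.na(coefs[, 1])
  new_mask <- mask
  new_mask[mask] <- good
  if (dropped > 0L)
    warning(dropped, " voxel(s) excluded: fewer than 7 usable measurements")
  tf <- tensor_field(coefs[good, 2:7, drop = FALSE], new_mask, ds$affine,
                     s0 = exp(coefs[good, 1]))
  attr(tf, "n_dropped_voxels") <- dropped
  tf
}

#' Residual bootstrap of the tensor fit
#'
#' Resamples whole-model log-signal residuals with replacement per voxel,
#' refits the log-linear model \code{n_boot} times, and reports the mean
#' tensor together with the bootstrap standard deviation of FA, MD, AD and RD
#' per voxel.
#'
#' @inheritParams fit_tensor_lls
#' @param n_boot number of bootstrap replicates (default 500).
#' @param seed integer seed controlling the resampling.
#' @return list with \code{mean_field} (a [tensor_field()] of replicate-mean
#'   tensors), \code{sd} (named list of 3D arrays: fa, md, ad, rd),
#'   \code{point_field} (the plain fit) and \code{n_boot}.
#' @export
bootstrap_tensor <- function(ds, mask = NULL, n_boot = 500L, seed = 1L) {
  if (n_boot < 2L) stop("n_boot must be at least 2")
  point <- fit_tensor_lls(ds, mask)
  mask <- point$mask
  g <- ds$gradients
  X <- tensor_design(g)
  proj <- solve(crossprod(X), t(X))
  nvol <- length(g)
  sig <- matrix(ds$signal, ncol = nvol)[as.vector(mask), , drop = FALSE]
  usable <- rowSums(sig > 0) == nvol
  n <- nrow(sig)

  logS <- log(pmax(sig, .Machine$double.eps))
  fitted <- t(X %*% rbind(log(point$s0), t(point$coef)))  # n x nvol
  resid <- logS - fitted

  acc <- matrix(0, n, 6)
  # running variance accumulators, centred on the point-fit measures to
  # avoid catastrophic cancellation when the spread is tiny
  m_ref <- eigen_measures(point$coef)
  sums <- matrix(0, n, 4); sq <- matrix(0, n, 4)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- matrix(sample.int(nvol, n * nvol, replace = TRUE), n, nvol)
    star <- fitted + resid[cbind(rep(seq_len(n), nvol), as.vector(idx))]
    dim(star) <- c(n, nvol)
    theta <- t(proj %*% t(star))            # n x 7
    cf <- theta[, 2:7, drop = FALSE]
    acc <- acc + cf
    m <- eigen_measures(cf) - m_ref
    sums <- sums + m; sq <- sq + m^2
  }
  mean_cf <- acc / n_boot
  sd_m <- sqrt(pmax(sq / n_boot - (sums / n_boot)^2, 0) *
                 n_boot / (n_boot - 1))
  if (any(!usable))
    warning(sum(!usable), " voxel(s) bootstrapped on clamped log-signal")
  to_arr <- function(v) { a <- array(NA_real_, dim(mask)); a[mask] <- v; a }
  list(mean_field = tensor_field(mean_cf, mask, ds$affine),
       sd = list(fa = to_arr(sd_m[, 1]), md = to_arr(sd_m[, 2]),
                 ad = to_arr(sd_m[, 3]), rd = to_arr(sd_m[, 4])),
       point_field = point, n_boot = as.integer(n_boot))
}

# FA/MD/AD/RD per row of a component matrix (vectorized eigenvalues via eigen
# loop; used by the bootstrap where only measures, not vectors, are needed)
eigen_measures <- function(coef) {
  n <- nrow(coef)
  out <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    ev <- eigen(as_tensor_matrix(coef[i, ]), symmetric = TRUE,
                only.values = TRUE)$values
    out[i, ] <- c(fa_from_evals(ev[1], ev[2], ev[3]),
                  mean(ev), ev[1], (ev[2] + ev[3]) / 2)
  }
  out
}

#' Fractional anisotropy from sorted eigenvalues
#'
#' \code{FA = sqrt(3/2) * ||lambda - mean|| / ||lambda||}; negative
#' eigenvalues are clamped to zero before evaluation and an all-zero tensor
#' has FA 0 by definition.
#' @param l1,l2,l3 eigenvalues (any order).
#' @return FA in [0, 1].
#' @export
fa_from_evals <- function(l1, l2, l3) {
  l1 <- pmax(l1, 0); l2 <- pmax(l2, 0); l3 <- pmax(l3, 0)
  ss <- l1^2 + l2^2 + l3^2
  m <- (l1 + l2 + l3) / 3
  dev <- (l1 - m)^2 + (l2 - m)^2 + (l3 - m)^2
  fa <- ifelse(ss > 0, sqrt(1.5 * dev / ss), 0)
  pmin(pmax(fa, 0), 1)
}

#' Analytic FA of an axially symmetric tensor
#'
#' Closed form for eigenvalues (ad, rd, rd):
#' \code{(ad - rd) / sqrt(ad^2 + 2 rd^2)}.
#' @param ad axial diffusivity (largest eigenvalue).
#' @param rd radial diffusivity (the two equal minor eigenvalues).
#' @return FA in [0, 1].
#' @export
fa_axial <- function(ad, rd) (ad - rd) / sqrt(ad^2 + 2 * rd^2)

#' Scalar diffusion maps from a tensor field
#'
#' FA, MD, AD and RD volumes on the grid of the tensor field (NA outside the
#' mask).  MD = (lambda1+lambda2+lambda3)/3, AD = lambda1,
#' RD = (lambda2+lambda3)/2; negative eigenvalues are clamped to zero for FA
#' only, so the identity MD = (AD + 2 RD)/3 holds exactly everywhere.
#'
#' @param tf a [tensor_field()].
#' @return object of class \code{scalar_maps}: list of 3D arrays
#'   \code{fa, md, ad, rd} plus the affine; attribute \code{n_clamped}
#'   counts voxels where clamping occurred.
#' @export
scalar_maps <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  ev <- tf$evals
  to_arr <- function(v) { a <- array(NA_real_, tf$dim); a[tf$mask] <- v; a }
  maps <- list(fa = to_arr(fa_from_evals(ev[, 1], ev[, 2], ev[, 3])),
               md = to_arr(rowMeans(ev)),
               ad = to_arr(ev[, 1]),
               rd = to_arr((ev[, 2] + ev[, 3]) / 2),
               affine = tf$affine)
  class(maps) <- "scalar_maps"
  attr(maps, "n_clamped") <- sum(ev[, 3] < 0)
  maps
}

#' @export
print.scalar_maps <- function(x, ...) {
  msk <- !is.na(x$fa)
  cat("<scalar_maps> ", paste(dim(x$fa), collapse = "x"), " grid, ",
      sum(msk), " voxels; mean FA ", format(mean(x$fa[msk]), digits = 3),
      ", mean MD ", format(mean(x$md[msk]), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Write scalar maps as NIfTI volumes
#'
#' Writes \code{fa.nii.gz}, \code{md.nii.gz}, \code{ad.nii.gz},
#' \code{rd.nii.gz} (and any supplied bootstrap SD maps as
#' \code{<measure>_sd.nii.gz}) sharing the input affine.
#'
#' @param maps a [scalar_maps()] object.
#' @param dir output directory (created if needed).
#' @param sd optional named list of SD arrays as returned by
#'   [bootstrap_tensor()].
#' @return invisibly, the paths written.
#' @export
write_scalar_maps <- function(maps, dir, sd = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write1 <- function(arr, path) {
    arr[is.na(arr)] <- 0
    img <- RNifti::asNifti(arr, datatype = "float")
    RNifti::sform(img) <- structure(maps$affine, code = 2L)
    RNifti::writeNifti(img, path)
    path
  }
  paths <- c(
    fa = write1(maps$fa, file.path(dir, "fa.nii.gz")),
    md = write1(maps$md, file.path(dir, "md.nii.gz")),
    ad = write1(maps$ad, file.path(dir, "ad.nii.gz")),
    rd = write1(maps$rd, file.path(dir, "rd.nii.gz")))
  for (nm in names(sd))
    paths[paste0(nm, "_sd")] <-
      write1(sd[[nm]], file.path(dir, paste0(nm, "_sd.nii.gz")))
  invisible(paths)
}
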