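# Synthetic orbital DWI phantoms: a curved tubular nerve of known
# ground-truth tensors inside an isotropic (CSF-like) surround, imaged with
# the monoexponential tensor signal model plus Rician noise.

#' Specification of a single-nerve orbital DWI phantom
#'
#' Defaults emulate a whole-orbit acquisition at 2 mm isotropic resolution
#' containing a gently S-curved tubular optic nerve about 25 mm long and
#' 4 mm in diameter.  Diffusivities are on the printed clinical scale
#' (numerically 10^-3 mm^2/s); the healthy default profile is
#' AD 0.955 / RD 0.510 and the surround is isotropic with MD 3.0.
#'
#' @param grid_shape integer triple of voxel counts.
#' @param voxel_size isotropic voxel edge in mm.
#' @param centerline_ctrl_points n x 3 matrix of mm control points for the
#'   nerve centerline; \code{NULL} uses a default S-curve through the grid
#'   centre, 25 mm end to end with 1.5 mm lateral amplitude.
#' @param tube_radius nerve tube radius in mm (default 2, i.e. 4 mm diameter).
#' @param nerve_ad,nerve_rd axial / radial diffusivity of the nerve tissue.
#' @param background_md isotropic diffusivity of the surround.
#' @param s0 baseline (b0) signal level, arbitrary units.
#' @param snr baseline-signal-to-noise-sigma ratio; \code{Inf} disables noise.
#' @param seed integer seed for the noise draw.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 33L), voxel_size = 2.0,
                         centerline_ctrl_points = NULL, tube_radius = 2.0,
                         nerve_ad = 0.955, nerve_rd = 0.510,
                         background_md = 3.0, s0 = 1000, snr = 20,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L), voxel_size > 0)
  if (!(nerve_ad >= nerve_rd && nerve_rd > 0))
    stop("need nerve_ad >= nerve_rd > 0")
  if (tube_radius <= 0) stop("tube_radius must be > 0")
  if (!(snr > 0)) stop("snr must be > 0 (Inf for noiseless)")
  if (s0 < 0) stop("s0 must be non-negative")
  if (background_md <= 0) stop("background_md must be > 0")
  extent <- (grid_shape - 1L) * voxel_size
  if (is.null(centerline_ctrl_points)) {
    ctr <- extent / 2
    half <- 12.5
    u <- c(-half, -half / 3, half / 3, half)
    centerline_ctrl_points <- cbind(ctr[1] + 1.5 * sin(pi * u / half / 1.25),
                                    ctr[2] + u,
                                    rep(ctr[3], 4))
  }
  cp <- rbind_point(centerline_ctrl_points)
  if (nrow(cp) < 2L) stop("centerline needs at least 2 control points")
  for (ax in 1:3)
    if (any(cp[, ax] < tube_radius | cp[, ax] > extent[ax] - tube_radius))
      stop("centerline control points must keep a tube_radius margin ",
           "from the grid boundary")
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 centerline_ctrl_points = cp, tube_radius = tube_radius,
                 nerve_ad = nerve_ad, nerve_rd = nerve_rd,
                 background_md = background_md, s0 = s0, snr = snr,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> grid ", paste(x$grid_shape, collapse = "x"), " @ ",
      x$voxel_size, " mm; nerve AD/RD ", x$nerve_ad, "/", x$nerve_rd,
      ", tube r = ", x$tube_radius, " mm; SNR ", x$snr, "\n", sep = "")
  invisible(x)
}

phantom_affine <- function(spec)
  diag(c(rep(spec$voxel_size, 3), 1))

# ---- centerline geometry ---------------------------------------------------

# uniform Catmull-Rom spline through the control points, densely sampled
catmull_rom_dense <- function(cp, per_segment = 100L) {
  m <- nrow(cp)
  if (m == 2L) {
    t <- seq(0, 1, length.out = per_segment + 1L)
    return(cbind(cp[1, 1] + t * (cp[2, 1] - cp[1, 1]),
                 cp[1, 2] + t * (cp[2, 2] - cp[1, 2]),
                 cp[1, 3] + t * (cp[2, 3] - cp[1, 3])))
  }
  pad <- rbind(2 * cp[1, ] - cp[2, ], cp, 2 * cp[m, ] - cp[m - 1, ])
  out <- NULL
  for (i in seq_len(m - 1L)) {
    p0 <- pad[i, ]; p1 <- pad[i + 1, ]; p2 <- pad[i + 2, ]; p3 <- pad[i + 3, ]
    t <- seq(0, 1, length.out = per_segment + 1L)
    if (i < m - 1L) t <- t[-length(t)]
    t2 <- t^2; t3 <- t^3
    seg <- 0.5 * (outer(rep(1, length(t)), 2 * p1) +
                    outer(t, -p0 + p2) +
                    outer(t2, 2 * p0 - 5 * p1 + 4 * p2 - p3) +
                    outer(t3, -p0 + 3 * p1 - 3 * p2 + p3))
    out <- rbind(out, seg)
  }
  out
}

polyline_cumlen <- function(pts) {
  seg <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(seg))
}

# resample a polyline at the given arc-length positions (linear interpolation)
polyline_at <- function(pts, s) {
  cl <- polyline_cumlen(pts)
  s <- pmin(pmax(s, 0), cl[length(cl)])
  out <- matrix(NA_real_, length(s), 3)
  for (ax in 1:3)
    out[, ax] <- approx(cl, pts[, ax], xout = s, ties = "ordered")$y
  out
}

#' Build the nerve centerline of a phantom
#'
#' C1 Catmull-Rom interpolation through the control points, resampled at
#' 0.5 mm arc-length steps (the final point keeps the exact endpoint).
#'
#' @param spec a [phantom_spec()].
#' @return n x 3 matrix of mm points with attribute \code{arc_length}.
#' @export
make_centerline <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dense <- catmull_rom_dense(spec$centerline_ctrl_points)
  total <- polyline_cumlen(dense)
  total <- total[length(total)]
  s <- unique(c(seq(0, total, by = 0.5), total))
  pts <- polyline_at(dense, s)
  attr(pts, "arc_length") <- total
  pts
}

# ---- ground-truth tensors --------------------------------------------------

#' Construct the ground-truth tensor field of a phantom
#'
#' Voxels whose centre lies within \code{tube_radius} of the centerline get
#' an axially symmetric tensor with principal axis along the local centerline
#' tangent and eigenvalues (nerve_ad, nerve_rd, nerve_rd); all other voxels
#' get an isotropic tensor with eigenvalue \code{background_md}.
#'
#' @param spec a [phantom_spec()].
#' @param centerline optional precomputed [make_centerline()] result.
#' @return a [tensor_field()] covering the full grid, with attribute
#'   \code{in_tube} (logical 3D array).
#' @export
ground_truth_tensors <- function(spec, centerline = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(centerline)) centerline <- make_centerline(spec)
  d <- spec$grid_shape
  affine <- phantom_affine(spec)
  # voxel centres in mm
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  ctr <- vox_to_mm(idx, affine)
  nvox <- nrow(ctr)

  # nearest centerline sample per voxel (0.5 mm sampling makes the
  # point-vs-segment distance error negligible against a 2 mm radius)
  np <- nrow(centerline)
  best_d2 <- rep(Inf, nvox); best_i <- rep(1L, nvox)
  for (p in seq_len(np)) {
    d2 <- (ctr[, 1] - centerline[p, 1])^2 + (ctr[, 2] - centerline[p, 2])^2 +
      (ctr[, 3] - centerline[p, 3])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]; best_i[upd] <- p
  }
  in_tube <- best_d2 <= spec$tube_radius^2

  # tangents by central differences along the resampled centerline
  tang <- rbind(centerline[2, ] - centerline[1, ],
                centerline[-(1:2), , drop = FALSE] -
                  centerline[seq_len(np - 2), , drop = FALSE],
                centerline[np, ] - centerline[np - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))

  coef <- matrix(0, nvox, 6)
  evals <- matrix(spec$background_md, nvox, 3)
  evecs <- array(0, c(nvox, 3, 3))
  evecs[, 1, 1] <- 1; evecs[, 2, 2] <- 1; evecs[, 3, 3] <- 1
  coef[, 1:3] <- spec$background_md

  if (any(in_tube)) {
    tt <- tang[best_i[in_tube], , drop = FALSE]
    ad <- spec$nerve_ad; rd <- spec$nerve_rd
    # D = rd*I + (ad - rd) * t t'
    coef[in_tube, 1] <- rd + (ad - rd) * tt[, 1]^2
    coef[in_tube, 2] <- rd + (ad - rd) * tt[, 2]^2
    coef[in_tube, 3] <- rd + (ad - rd) * tt[, 3]^2
    coef[in_tube, 4] <- (ad - rd) * tt[, 1] * tt[, 2]
    coef[in_tube, 5] <- (ad - rd) * tt[, 1] * tt[, 3]
    coef[in_tube, 6] <- (ad - rd) * tt[, 2] * tt[, 3]
    evals[in_tube, 1] <- ad; evals[in_tube, 2:3] <- rd
    # principal axis = tangent; completing vectors via a stable perpendicular
    perp1 <- perpendicular_of(tt)
    perp2 <- cross3(tt, perp1)
    evecs[in_tube, , 1] <- tt
    evecs[in_tube, , 2] <- perp1
    evecs[in_tube, , 3] <- perp2
  }
  mask <- array(TRUE, d)
  tf <- tensor_field(coef, mask, affine, evals = evals, evecs = evecs)
  it <- array(in_tube, d)
  attr(tf, "in_tube") <- it
  attr(tf, "centerline") <- centerline
  tf
}

# a unit vector perpendicular to each row of v (rows are unit vectors)
perpendicular_of <- function(v) {
  helper <- matrix(rep(c(0, 0, 1), each = nrow(v)), ncol = 3)
  near_z <- abs(v[, 3]) > 0.9
  helper[near_z, ] <- matrix(rep(c(1, 0, 0), each = sum(near_z)), ncol = 3)
  p <- cross3(v, helper)
  p / sqrt(rowSums(p^2))
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# ---- gradient scheme -------------------------------------------------------

#' Generate a diffusion gradient scheme by electrostatic repulsion
#'
#' Unit directions are initialized from a seeded uniform draw on the sphere
#' and relaxed by antipodally symmetric Coulomb repulsion.
#'
#' @param n_dirs number of directions.
#' @param seed integer seed.
#' @param n_iter relaxation iterations.
#' @return n_dirs x 3 matrix of unit vectors.
#' @export
make_gradient_scheme <- function(n_dirs = 48L, seed = 42L, n_iter = 600L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  v <- matrix(rnorm(n_dirs * 3), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  step <- 0.05
  for (it in seq_len(n_iter)) {
    f <- matrix(0, n_dirs, 3)
    for (i in seq_len(n_dirs)) {
      d_plus <- sweep(v, 2, v[i, ])           # v - v_i
      d_minus <- sweep(v, 2, -v[i, ])         # v + v_i (antipode)
      r2p <- rowSums(d_plus^2); r2m <- rowSums(d_minus^2)
      r2p[i] <- Inf; r2m <- pmax(r2m, 1e-12)
      f[i, ] <- -colSums(d_plus / (r2p^1.5)) + colSums(d_minus / (r2m^1.5))
    }
    # tangential force with a capped per-point displacement keeps the
    # 1/r^2 divergence from slingshotting close pairs past each other
    f <- f - v * rowSums(f * v)
    nf <- sqrt(rowSums(f^2))
    v <- v + f * (pmin(step, step * nf) / pmax(nf, 1e-12))
    v <- v / sqrt(rowSums(v^2))
    step <- step * 0.995
  }
  v
}

#' Default 48-direction, b = 2000 gradient table with an AP/PA b0 pair
#'
#' Loads the electrostatically distributed 48-direction scheme shipped with
#' the package and prepends two b0 volumes tagged AP and PA, giving the
#' 50-volume acquisition layout (2 b0 + 48 DWI).
#'
#' @param b diffusion weighting in s/mm^2 (default 2000).
#' @return a [gradient_table()] with 50 entries.
#' @export
default_gradients <- function(b = 2000) {
  path <- system.file("extdata", "dirs48.txt", package = "ondti",
                      mustWork = TRUE)
  dirs <- as.matrix(read.table(path))
  gradient_table(c(0, 0, rep(b, nrow(dirs))),
                 rbind(0, 0, dirs),
                 c("AP", "PA", rep("none", nrow(dirs))))
}

# ---- signal simulation -----------------------------------------------------

#' Simulate DWI signal from a tensor field
#'
#' Noiseless signal per volume is \code{S = S0 exp(-b g' D g)} with b in
#' s/mm^2 and D converted from the printed scale to mm^2/s.  Rician noise is
#' applied as \code{|S + e1 + i e2|} with independent
#' \code{e ~ N(0, (S0/snr)^2)}; \code{snr = Inf} gives the noiseless signal.
#'
#' @param tensors a [tensor_field()] covering the full grid.
#' @param gradients a [gradient_table()].
#' @param s0 baseline signal (>= 0).
#' @param snr baseline-to-noise-sigma ratio; Inf for noiseless.
#' @param seed integer seed for the noise draw.
#' @param noise \code{"rician"} (default) or \code{"gaussian"} (analytic
#'   tests; negative values clamped to 0).
#' @return a [dwi_dataset()].
#' @export
simulate_signal <- function(tensors, gradients, s0 = 1000, snr = 20,
                            seed = 1L, noise = c("rician", "gaussian")) {
  stopifnot(inherits(tensors, "tensor_field"),
            inherits(gradients, "gradient_table"))
  noise <- match.arg(noise)
  if (s0 < 0) stop("s0 must be non-negative")
  if (!(snr > 0)) stop("snr must be > 0")
  if (!all(tensors$mask)) stop("tensor field must cover the full grid")
  d <- tensors$dim
  nvox <- prod(d); nvol <- length(gradients)
  cf <- tensors$coef
  g <- gradients$bvecs; b <- gradients$bvals * DIFF_UNIT
  S <- matrix(0, nvox, nvol)
  for (v in seq_len(nvol)) {
    q <- g[v, 1]^2 * cf[, 1] + g[v, 2]^2 * cf[, 2] + g[v, 3]^2 * cf[, 3] +
      2 * (g[v, 1] * g[v, 2] * cf[, 4] + g[v, 1] * g[v, 3] * cf[, 5] +
             g[v, 2] * g[v, 3] * cf[, 6])
    S[, v] <- s0 * exp(-b[v] * q)
  }
  if (is.finite(snr)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    sigma <- s0 / snr
    if (noise == "rician") {
      e1 <- matrix(rnorm(nvox * nvol, sd = sigma), nvox, nvol)
      e2 <- matrix(rnorm(nvox * nvol, sd = sigma), nvox, nvol)
      S <- sqrt((S + e1)^2 + e2^2)
    } else {
      S <- pmax(S + matrix(rnorm(nvox * nvol, sd = sigma), nvox, nvol), 0)
    }
  }
  dim(S) <- c(d, nvol)
  dwi_dataset(S, tensors$affine, gradients)
}

# ---- ROI placement ---------------------------------------------------------

#' Place the two tracking ROIs along a centerline
#'
#' Two 3 mm radius spheres at 5\% (retrobulbar, optic-nerve-head end) and
#' 95\% (orbital apex end) of the centerline arc length.
#'
#' @param centerline n x 3 mm polyline (from [make_centerline()]).
#' @param radius sphere radius in mm.
#' @return list of two [roi_sphere()]s named \code{onh} and \code{apex}.
#' @export
place_rois <- function(centerline, radius = 3.0) {
  cl <- polyline_cumlen(centerline)
  total <- cl[length(cl)]
  if (total <= 10) stop("centerline too short for ROI placement (<= 10 mm)")
  ctrs <- polyline_at(centerline, c(0.05, 0.95) * total)
  list(onh = roi_sphere(ctrs[1, ], radius),
       apex = roi_sphere(ctrs[2, ], radius))
}

#' Build a complete single-nerve phantom
#'
#' Convenience wrapper: centerline, ground-truth tensors, ROI spheres and the
#' simulated acquisition (two AP/PA b0 volumes + 48 directions at b = 2000 by
#' default).
#'
#' @param spec a [phantom_spec()].
#' @param gradients a [gradient_table()]; default [default_gradients()].
#' @param noise noise model passed to [simulate_signal()].
#' @return list with \code{dwi}, \code{truth} (tensor field), \code{centerline},
#'   \code{rois}, \code{spec}.
#' @export
make_phantom <- function(spec = phantom_spec(), gradients = default_gradients(),
                         noise = "rician") {
  cl <- make_centerline(spec)
  truth <- ground_truth_tensors(spec, cl)
  dwi <- simulate_signal(truth, gradients, s0 = spec$s0, snr = spec$snr,
                         seed = spec$seed, noise = noise)
  list(dwi = dwi, truth = truth, centerline = cl,
       rois = place_rois(cl), spec = spec)
}

#' Write the ground-truth eigensystem as a 5-volume NIfTI
#'
#' Volumes: lambda1, lambda2, lambda3, and the polar angles (theta, phi) of
#' the principal axis.
#' @param truth a ground-truth [tensor_field()].
#' @param path output NIfTI path.
#' @return invisibly, the path.
#' @export
save_ground_truth <- function(truth, path) {
  d <- truth$dim
  e1 <- truth$evecs[, , 1]
  arr <- array(0, c(d, 5))
  put <- function(k, v) { a <- array(0, d); a[truth$mask] <- v; arr[, , , k] <<- a }
  put(1, truth$evals[, 1]); put(2, truth$evals[, 2]); put(3, truth$evals[, 3])
  put(4, acos(pmin(pmax(e1[, 3], -1), 1)))
  put(5, atan2(e1[, 2], e1[, 1]))
  img <- RNifti::asNifti(arr, datatype = "float")
  RNifti::sform(img) <- structure(truth$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
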