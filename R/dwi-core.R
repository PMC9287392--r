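#' @importFrom stats rnorm runif sd var cor cov coef quantile approx setNames
#'   wilcox.test chisq.test anova aggregate as.formula model.matrix
#'   format.pval
#' @importFrom utils head tail read.csv write.csv read.table
NULL

# Coordinate convention used package-wide: RAS+ millimetres, 0-based voxel
# indices, voxel centres at integer indices.  mm = affine %*% c(i, j, k, 1).

#' Gradient table for a diffusion acquisition
#'
#' Holds one b-value and one unit gradient direction per 4D volume, plus the
#' phase-encoding tag of each b0 volume (\code{"AP"}, \code{"PA"} or
#' \code{"none"}).  Directions with b > 0 must have unit Euclidean norm;
#' b0 directions are the zero vector.
#'
#' @param bvals numeric vector of b-values in s/mm^2.
#' @param bvecs numeric matrix, one row per volume, columns x/y/z
#'   (scanner frame).
#' @param phase_dir character vector with one entry per volume;
#'   b0 volumes carry \code{"AP"}/\code{"PA"} (or \code{"none"}),
#'   diffusion-weighted volumes always \code{"none"}.
#' @return an object of class \code{gradient_table}.
#' @export
gradient_table <- function(bvals, bvecs, phase_dir = NULL) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L)
    stop("bvecs must have three columns (x, y, z)")
  if (length(bvals) != nrow(bvecs))
    stop("gradient table mismatch: ", length(bvals), " b-values vs ",
         nrow(bvecs), " directions")
  if (is.null(phase_dir)) phase_dir <- rep("none", length(bvals))
  phase_dir <- as.character(phase_dir)
  if (length(phase_dir) != length(bvals))
    stop("phase_dir must have one entry per volume")
  if (!all(phase_dir %in% c("AP", "PA", "none")))
    stop("phase_dir entries must be 'AP', 'PA' or 'none'")

  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > 0
  if (any(dw)) {
    off <- abs(nrm[dw] - 1)
    if (any(off > 1e-3))
      stop("non-unit gradient direction at b > 0 (norm deviates by ",
           format(max(off)), ")")
    # re-normalize directions that are within 1e-3 of unit norm
    bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm[dw]
  }
  if (any(!dw)) {
    if (any(nrm[!dw] > 1e-6))
      stop("b0 volumes must carry the zero gradient vector")
    bvecs[!dw, ] <- 0
  }
  structure(list(bvals = bvals, bvecs = unname(bvecs), phase_dir = phase_dir),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  nb0 <- sum(x$bvals == 0)
  cat("<gradient_table> ", length(x$bvals), " volumes: ",
      length(x$bvals) - nb0, " DWI (b = ",
      paste(unique(x$bvals[x$bvals > 0]), collapse = "/"),
      " s/mm2), ", nb0, " b0 [",
      paste(x$phase_dir[x$bvals == 0], collapse = ","), "]\n", sep = "")
  invisible(x)
}

#' @export
length.gradient_table <- function(x) length(x$bvals)

#' Diffusion-weighted imaging dataset
#'
#' A 4D signal array with its voxel-to-mm affine and gradient table.
#' Signal is non-negative and in arbitrary scanner units; the affine maps
#' 0-based voxel indices (voxel centres at integers) to RAS+ mm.
#'
#' @param signal 4D numeric array (x, y, z, volume), values >= 0.
#' @param affine 4x4 invertible voxel-to-mm matrix.
#' @param gradients a [gradient_table()] with one entry per volume.
#' @return an object of class \code{dwi_dataset}.
#' @export
dwi_dataset <- function(signal, affine, gradients) {
  if (length(dim(signal)) != 4L)
    stop("signal must be a 4D array")
  if (dim(signal)[4] < 1L) stop("dataset must contain at least one volume")
  if (any(signal < 0)) stop("signal values must be non-negative")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12)
    stop("affine is not invertible")
  if (!inherits(gradients, "gradient_table"))
    stop("gradients must be a gradient_table")
  if (length(gradients) != dim(signal)[4])
    stop("volume count mismatch: ", dim(signal)[4], " volumes vs ",
         length(gradients), " gradient entries")
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(signal = signal, affine = affine, gradients = gradients,
                 voxel_size = voxel_size),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$signal)
  cat("<dwi_dataset> ", paste(d[1:3], collapse = "x"), " voxels x ", d[4],
      " volumes, voxel ", paste(format(x$voxel_size, digits = 3),
                                collapse = "x"), " mm\n", sep = "")
  print(x$gradients)
  invisible(x)
}

#' Spherical region of interest
#'
#' @param center length-3 numeric, RAS+ mm.
#' @param radius sphere radius in mm (> 0).
#' @return an object of class \code{roi_sphere}.
#' @export
roi_sphere <- function(center, radius) {
  center <- as.numeric(center)
  if (length(center) != 3L) stop("center must be a length-3 mm coordinate")
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  structure(list(center = center, radius = radius), class = "roi_sphere")
}

# ---- coordinate helpers ----------------------------------------------------

#' Convert mm coordinates to continuous 0-based voxel coordinates
#' @param pts n x 3 matrix (or length-3 vector) of RAS+ mm points.
#' @param affine 4x4 voxel-to-mm matrix.
#' @return n x 3 matrix of voxel coordinates.
#' @keywords internal
mm_to_vox <- function(pts, affine) {
  pts <- rbind_point(pts)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(pts) + inv[1:3, 4])
}

#' Convert 0-based voxel coordinates to RAS+ mm
#' @keywords internal
vox_to_mm <- function(vox, affine) {
  vox <- rbind_point(vox)
  t(affine[1:3, 1:3] %*% t(vox) + affine[1:3, 4])
}

rbind_point <- function(p) {
  if (is.null(dim(p))) matrix(as.numeric(p), ncol = 3) else as.matrix(p)
}

# ---- I/O -------------------------------------------------------------------

#' Load a diffusion dataset from NIfTI + FSL bval/bvec files
#'
#' Reads a 4D NIfTI-1 volume together with FSL-dialect gradient files
#' (bvals: one whitespace-separated row; bvecs: three rows of x, y, z) and an
#' optional JSON sidecar carrying the phase-encoding tags of the b0 volumes
#' as \code{{"b0_phase": ["AP", "PA"]}} in acquisition order.
#'
#' @param nifti_path path to the 4D .nii/.nii.gz file.
#' @param bval_path,bvec_path paths to the FSL gradient text files.
#' @param json_path optional sidecar JSON path; defaults to
#'   \code{<nifti stem>.json} if that file exists.
#' @return a [dwi_dataset()].
#' @export
load_dwi <- function(nifti_path, bval_path, bvec_path, json_path = NULL) {
  for (p in c(nifti_path, bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p)
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))

  bvals <- scan(bval_path, quiet = TRUE)
  bvec_rows <- as.matrix(read.table(bvec_path))
  if (nrow(bvec_rows) != 3L)
    stop("bvec file must contain 3 rows (FSL dialect): ", bvec_path)
  bvecs <- t(bvec_rows)
  nvol <- dim(arr)[4]
  if (length(bvals) != nvol || nrow(bvecs) != nvol)
    stop("volume count mismatch: NIfTI has ", nvol, " volumes, bval has ",
         length(bvals), ", bvec has ", nrow(bvecs))

  phase <- rep("none", nvol)
  if (is.null(json_path)) {
    cand <- sub("\\.nii(\\.gz)?$", ".json", nifti_path)
    if (file.exists(cand)) json_path <- cand
  }
  if (!is.null(json_path) && file.exists(json_path)) {
    side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    if (!is.null(side$b0_phase)) {
      idx <- which(bvals == 0)
      tags <- as.character(side$b0_phase)
      if (length(tags) != length(idx))
        stop("sidecar lists ", length(tags), " b0 phase tags but dataset has ",
             length(idx), " b0 volumes")
      phase[idx] <- tags
    }
  }
  dwi_dataset(arr, affine, gradient_table(bvals, bvecs, phase))
}

#' Save a diffusion dataset as NIfTI + FSL bval/bvec (+ JSON sidecar)
#'
#' Signal is stored as float32; bvals/bvecs round-trip bit-identically
#' through [load_dwi()].  A sidecar JSON with the b0 phase tags is written
#' next to the NIfTI when any b0 volume carries an AP/PA tag.
#'
#' @param ds a [dwi_dataset()].
#' @param nifti_path,bval_path,bvec_path output paths.
#' @return invisibly, a named character vector of the files written.
#' @export
save_dwi <- function(ds, nifti_path, bval_path, bvec_path) {
  stopifnot(inherits(ds, "dwi_dataset"))
  img <- RNifti::asNifti(ds$signal, datatype = "float")
  RNifti::sform(img) <- structure(ds$affine, code = 2L)
  ok <- try(RNifti::writeNifti(img, nifti_path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write NIfTI: ", nifti_path)
  writeLines(paste(format(ds$gradients$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  bv <- t(ds$gradients$bvecs)  # 3 rows of x, y, z
  writeLines(apply(bv, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec_path)
  paths <- c(nifti = nifti_path, bval = bval_path, bvec = bvec_path)
  idx <- which(ds$gradients$bvals == 0)
  if (length(idx) && any(ds$gradients$phase_dir[idx] != "none")) {
    jp <- sub("\\.nii(\\.gz)?$", ".json", nifti_path)
    jsonlite::write_json(list(b0_phase = ds$gradients$phase_dir[idx]), jp,
                         auto_unbox = FALSE)
    paths <- c(paths, json = jp)
  }
  invisible(paths)
}

#' Merge opposed-phase b0 volumes into one corrected b0
#'
#' Replaces all AP/PA-tagged b0 volumes by their voxel-wise arithmetic mean,
#' placed as the first volume of the output; diffusion-weighted volumes are
#' carried over unchanged, so a 48-direction acquisition with an AP/PA b0
#' pair yields the corrected 49-volume dataset.
#'
#' @param ds a [dwi_dataset()] containing at least one AP- and one PA-tagged
#'   b0 volume.
#' @return a [dwi_dataset()] with \code{n_dwi + 1} volumes.
#' @export
merge_b0_pairs <- function(ds) {
  stopifnot(inherits(ds, "dwi_dataset"))
  g <- ds$gradients
  is_b0 <- g$bvals == 0
  if (!any(is_b0 & g$phase_dir == "AP") || !any(is_b0 & g$phase_dir == "PA"))
    stop("merge_b0_pairs requires at least one AP- and one PA-tagged b0 volume")
  b0_idx <- which(is_b0)
  dwi_idx <- which(!is_b0)
  d <- dim(ds$signal)
  b0s <- ds$signal[, , , b0_idx, drop = FALSE]
  merged <- apply(b0s, 1:3, mean)
  out <- array(0, c(d[1:3], length(dwi_idx) + 1L))
  out[, , , 1L] <- merged
  if (length(dwi_idx))
    out[, , , -1L] <- ds$signal[, , , dwi_idx, drop = FALSE]
  gt <- gradient_table(c(0, g$bvals[dwi_idx]),
                       rbind(c(0, 0, 0), g$bvecs[dwi_idx, , drop = FALSE]),
                       c("none", rep("none", length(dwi_idx))))
  dwi_dataset(out, ds$affine, gt)
}
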