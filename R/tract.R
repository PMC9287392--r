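# ROI-to-ROI probabilistic tractography through a tensor field.
#
# Step directions are drawn from a Watson-style axial distribution centred on
# the local principal eigenvector, with concentration kappa = kappa0 * FA,
# so that coherent (high-FA) tissue steers sharply while near-isotropic
# voxels diffuse.  The same angular model scores candidates, which keeps
# generation and selection consistent.

#' A fiber bundle
#'
#' @param streamlines list of n x 3 mm point matrices, each oriented so the
#'   first point is at the ONH (roi1) end.
#' @param provenance one of \code{"candidates"}, \code{"selected"},
#'   \code{"cleaned"}.
#' @param scores optional per-streamline log-likelihood scores.
#' @param creation_index integer ids fixing tie-break order.
#' @return an object of class \code{fiber_bundle}.
#' @export
fiber_bundle <- function(streamlines, provenance, scores = NULL,
                         creation_index = seq_along(streamlines)) {
  stopifnot(provenance %in% c("candidates", "selected", "cleaned"))
  for (s in streamlines)
    if (nrow(s) < 2L) stop("every streamline needs at least 2 points")
  structure(list(streamlines = streamlines, provenance = provenance,
                 scores = scores, creation_index = creation_index),
            class = "fiber_bundle")
}

#' @export
length.fiber_bundle <- function(x) length(x$streamlines)

#' @export
print.fiber_bundle <- function(x, ...) {
  lens <- vapply(x$streamlines, streamline_length, 0)
  cat("<fiber_bundle> ", length(x), " streamlines (", x$provenance,
      "), length ", format(mean(lens), digits = 4), " +/- ",
      format(sd(lens), digits = 3), " mm\n", sep = "")
  invisible(x)
}

#' Arc length of a streamline
#' @param s n x 3 point matrix.
#' @return total length in mm.
#' @export
streamline_length <- function(s) sum(sqrt(rowSums(diff(s)^2)))

# ---- Watson-style angular model -------------------------------------------

# draw t = cos(angle to axis) from density proportional to exp(kappa t^2)
# on [-1, 1]; vectorized rejection sampling
rwatson_t <- function(kappa) {
  n <- length(kappa)
  t_out <- rep(NA_real_, n)
  todo <- seq_len(n)
  while (length(todo)) {
    t <- runif(length(todo), -1, 1)
    acc <- runif(length(todo)) < exp(kappa[todo] * (t^2 - 1))
    t_out[todo[acc]] <- t[acc]
    todo <- todo[!acc]
  }
  t_out
}

# log normalization constant: Z = 2*pi * integral_{-1}^{1} exp(kappa t^2) dt.
# The integrand peaks sharply at |t| = 1 for large kappa, so each grid value
# is computed by adaptive quadrature on exp(kappa(t^2 - 1)) and the function
# is evaluated through an interpolating spline cached per session.
.watson_env <- new.env(parent = emptyenv())

watson_spline <- function(kmax) {
  cur <- .watson_env$kmax
  if (is.null(cur) || kmax > cur) {
    kmax <- max(kmax, 256)
    grid <- seq(0, kmax, length.out = 2048L)
    vals <- vapply(grid, function(k)
      k + log(2 * pi * stats::integrate(function(x) exp(k * (x^2 - 1)),
                                        -1, 1, rel.tol = 1e-12)$value), 0)
    .watson_env$fun <- stats::splinefun(grid, vals, method = "natural")
    .watson_env$kmax <- kmax
  }
  .watson_env$fun
}

log_watson_norm <- function(kappa) {
  if (!length(kappa)) return(numeric(0))
  watson_spline(max(kappa, 0))(pmax(kappa, 0))
}

# per-step log density of direction d given local axis/FA
watson_logpdf <- function(cos_t, kappa)
  kappa * cos_t^2 - log_watson_norm(kappa)

# ---- field lookups ---------------------------------------------------------

# nearest-voxel lookup of FA and principal axis for mm points (n x 3);
# returns list(fa, e1, inside)
field_lookup <- function(pts, tf, fa_vec) {
  vox <- round(mm_to_vox(pts, tf$affine))
  d <- tf$dim
  inside <- vox[, 1] >= 0 & vox[, 1] < d[1] &
    vox[, 2] >= 0 & vox[, 2] < d[2] &
    vox[, 3] >= 0 & vox[, 3] < d[3]
  fa <- rep(0, nrow(pts))
  e1 <- matrix(0, nrow(pts), 3); e1[, 1] <- 1
  if (any(inside)) {
    lin <- 1L + vox[inside, 1] + d[1] * (vox[inside, 2] + d[2] * vox[inside, 3])
    row <- tf$row_of_voxel[lin]
    ok <- !is.na(row)
    if (any(ok)) {
      ii <- which(inside)[ok]
      fa[ii] <- fa_vec[row[ok]]
      e1[ii, ] <- tf$evecs[row[ok], , 1]
    }
  }
  list(fa = fa, e1 = e1, inside = inside)
}

tf_fa_vector <- function(tf)
  fa_from_evals(tf$evals[, 1], tf$evals[, 2], tf$evals[, 3])

# ---- candidate generation --------------------------------------------------

#' Generate candidate streamlines between two ROI spheres
#'
#' Probabilistic streamlines are seeded uniformly inside \code{roi1} and
#' stepped forward: at each step the direction is drawn from the Watson-style
#' axial distribution around the local principal eigenvector (concentration
#' \code{kappa0 * FA}), redrawn while the turning angle exceeds
#' \code{max_angle_deg} (a bounded number of redraws, after which the
#' candidate fails).  A candidate is accepted when it enters \code{roi2}
#' before exceeding twice the straight-line ROI distance; generation repeats
#' until \code{n} acceptances or a \code{100 n} attempt cap.
#'
#' @param tf a [tensor_field()] covering the tracking region.
#' @param roi1 seeding ROI ([roi_sphere()]), the optic-nerve-head end.
#' @param roi2 target ROI.
#' @param n number of accepted candidates wanted (default 1000).
#' @param seed integer seed.
#' @param step_mm step size in mm.
#' @param max_angle_deg per-step curvature cap in degrees.
#' @param kappa0 concentration scale of the angular model.
#' @return a [fiber_bundle()] with provenance \code{"candidates"}; attribute
#'   \code{n_attempted} records the attempt count.
#' @export
generate_candidates <- function(tf, roi1, roi2, n = 1000L, seed = 1L,
                                step_mm = 1.0, max_angle_deg = 45,
                                kappa0 = 100) {
  stopifnot(inherits(tf, "tensor_field"), inherits(roi1, "roi_sphere"),
            inherits(roi2, "roi_sphere"))
  d <- tf$dim
  ext_lo <- vox_to_mm(c(0, 0, 0), tf$affine)
  ext_hi <- vox_to_mm(d - 1, tf$affine)
  for (roi in list(roi1, roi2))
    if (any(roi$center < pmin(ext_lo, ext_hi)) ||
        any(roi$center > pmax(ext_lo, ext_hi)))
      stop("ROI centre outside the image grid")

  fa_vec <- tf_fa_vector(tf)
  straight <- sqrt(sum((roi2$center - roi1$center)^2))
  len_cap <- 2 * straight
  max_steps <- ceiling(len_cap / step_mm) + 1L
  cos_cap <- cos(max_angle_deg * pi / 180)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  accepted <- vector("list", n)
  n_acc <- 0L; n_att <- 0L; att_cap <- 100L * n
  while (n_acc < n && n_att < att_cap) {
    m <- min(max(2L * (n - n_acc), 64L), att_cap - n_att)
    n_att <- n_att + m
    paths <- run_tracking_batch(m, tf, fa_vec, roi1, roi2, step_mm,
                                cos_cap, kappa0, len_cap, max_steps)
    for (p in paths) {
      if (n_acc >= n) break
      n_acc <- n_acc + 1L
      accepted[[n_acc]] <- p
    }
  }
  if (n_acc == 0L)
    stop("tracking failure: no candidate reached the target ROI ",
         "(onh -> apex) within ", att_cap, " attempts")
  if (n_acc < n)
    warning("only ", n_acc, " of ", n, " candidates accepted at attempt cap")
  bundle <- fiber_bundle(accepted[seq_len(n_acc)], "candidates",
                         creation_index = seq_len(n_acc))
  attr(bundle, "n_attempted") <- n_att
  bundle
}

# track one vectorized batch of m seeds; returns list of accepted paths
run_tracking_batch <- function(m, tf, fa_vec, roi1, roi2, step_mm, cos_cap,
                               kappa0, len_cap, max_steps) {
  # uniform seeds inside roi1 (rejection from the bounding cube)
  seeds <- matrix(NA_real_, m, 3)
  need <- seq_len(m)
  while (length(need)) {
    u <- matrix(runif(3 * length(need), -1, 1), ncol = 3) * roi1$radius
    ok <- rowSums(u^2) <= roi1$radius^2
    seeds[need[ok], ] <- sweep(u[ok, , drop = FALSE], 2, roi1$center, "+")
    need <- need[!ok]
  }
  paths <- array(NA_real_, c(m, max_steps + 1L, 3))
  paths[, 1, ] <- seeds
  lk <- field_lookup(seeds, tf, fa_vec)
  to_target <- sweep(-seeds, 2, roi2$center, "+")
  flip <- rowSums(lk$e1 * to_target) < 0
  prev <- lk$e1; prev[flip, ] <- -prev[flip, ]

  active <- lk$inside
  status <- rep(NA_integer_, m)   # 1 accepted, 0 failed
  status[!active] <- 0L
  arc <- rep(0, m)
  n_pts <- rep(1L, m)
  pos <- seeds

  for (k in seq_len(max_steps)) {
    idx <- which(active)
    if (!length(idx)) break
    lk <- field_lookup(pos[idx, , drop = FALSE], tf, fa_vec)
    kap <- kappa0 * lk$fa
    axis <- lk$e1
    aflip <- rowSums(axis * prev[idx, , drop = FALSE]) < 0
    axis[aflip, ] <- -axis[aflip, ]

    dir <- matrix(NA_real_, length(idx), 3)
    todo <- seq_along(idx)
    for (r in 1:8) {
      if (!length(todo)) break
      t <- rwatson_t(kap[todo])
      phi <- runif(length(todo), 0, 2 * pi)
      a <- axis[todo, , drop = FALSE]
      e_u <- perpendicular_of(a)
      e_v <- cross3(a, e_u)
      s <- sqrt(pmax(1 - t^2, 0))
      cand <- a * t + e_u * (s * cos(phi)) + e_v * (s * sin(phi))
      ok <- rowSums(cand * prev[idx[todo], , drop = FALSE]) >= cos_cap
      dir[todo[ok], ] <- cand[ok, , drop = FALSE]
      todo <- todo[!ok]
    }
    if (length(todo)) {            # curvature cap exhausted: candidate fails
      status[idx[todo]] <- 0L
      active[idx[todo]] <- FALSE
      keep <- setdiff(seq_along(idx), todo)
      idx <- idx[keep]; dir <- dir[keep, , drop = FALSE]
      if (!length(idx)) next
    }
    pos[idx, ] <- pos[idx, , drop = FALSE] + step_mm * dir
    prev[idx, ] <- dir
    arc[idx] <- arc[idx] + step_mm
    n_pts[idx] <- n_pts[idx] + 1L
    paths[cbind(rep(idx, 3), n_pts[idx], rep(1:3, each = length(idx)))] <-
      pos[idx, , drop = FALSE]

    inb <- field_lookup(pos[idx, , drop = FALSE], tf, fa_vec)$inside
    hit <- rowSums(sweep(pos[idx, , drop = FALSE], 2, roi2$center)^2) <=
      roi2$radius^2
    done_ok <- hit & inb
    dead <- (!inb | arc[idx] > len_cap) & !done_ok
    status[idx[done_ok]] <- 1L
    status[idx[dead]] <- 0L
    active[idx[done_ok | dead]] <- FALSE
  }
  status[is.na(status)] <- 0L
  lapply(which(status == 1L), function(i)
    paths[i, seq_len(n_pts[i]), , drop = TRUE])
}

# ---- scoring and selection -------------------------------------------------

#' Score candidates and keep the most likely fraction
#'
#' Each streamline is scored by the length-normalized sum over steps of the
#' log density of its step direction under the Watson-style angular model
#' evaluated on the local tensor (the same model used for generation).  The
#' top \code{ceiling(keep_frac * n)} streamlines are kept; ties are broken by
#' shorter arc length, then lower creation index.
#'
#' @param bundle a candidates [fiber_bundle()].
#' @param tf the [tensor_field()] used for generation.
#' @param keep_frac fraction to keep, in (0, 1].
#' @param kappa0 concentration scale (must match generation).
#' @return a [fiber_bundle()] with provenance \code{"selected"} and scores.
#' @export
score_and_select <- function(bundle, tf, keep_frac = 0.10, kappa0 = 100) {
  stopifnot(inherits(bundle, "fiber_bundle"))
  if (bundle$provenance != "candidates")
    stop("score_and_select expects a candidates bundle")
  if (length(bundle) == 0L) stop("empty bundle")
  if (!(keep_frac > 0 && keep_frac <= 1)) stop("keep_frac must be in (0, 1]")
  fa_vec <- tf_fa_vector(tf)
  scores <- vapply(bundle$streamlines, score_streamline, 0,
                   tf = tf, fa_vec = fa_vec, kappa0 = kappa0)
  lens <- vapply(bundle$streamlines, streamline_length, 0)
  ord <- order(-scores, lens, bundle$creation_index)
  keep <- ord[seq_len(ceiling(keep_frac * length(bundle)))]
  keep <- sort(keep)
  fiber_bundle(bundle$streamlines[keep], "selected",
               scores = scores[keep],
               creation_index = bundle$creation_index[keep])
}

score_streamline <- function(s, tf, fa_vec, kappa0) {
  seg <- diff(s)
  seg <- seg / sqrt(rowSums(seg^2))
  lk <- field_lookup(s[-nrow(s), , drop = FALSE], tf, fa_vec)
  kap <- kappa0 * lk$fa
  cos_t <- abs(rowSums(seg * lk$e1))
  mean(watson_logpdf(cos_t, kap))
}

# ---- outlier cleaning ------------------------------------------------------

#' Remove outlying fibers from a selected bundle
#'
#' AFQ-style cleaning: all fibers are resampled to \code{n_nodes} nodes; the
#' fiber core is the node-wise mean position with node-wise spatial
#' covariance; a fiber's core distance is its node-averaged Mahalanobis
#' distance to the core.  Fibers more than \code{core_sd} standard deviations
#' above the bundle-mean core distance, or more than \code{len_sd} standard
#' deviations longer than the mean fiber length, are removed; both rules are
#' iterated to convergence (at most \code{max_rounds} rounds).  A bundle with
#' zero spread (e.g. identical fibers) removes nothing.
#'
#' @param bundle a selected [fiber_bundle()] with at least 5 fibers.
#' @param core_sd Mahalanobis threshold in SD units (default 2.6).
#' @param len_sd length threshold in SD units (default 3).
#' @param n_nodes nodes used for the core computation.
#' @param max_rounds iteration cap.
#' @return a [fiber_bundle()] with provenance \code{"cleaned"}; attribute
#'   \code{n_removed} counts discarded fibers.
#' @export
clean_outliers <- function(bundle, core_sd = 2.6, len_sd = 3.0,
                           n_nodes = 20L, max_rounds = 5L) {
  stopifnot(inherits(bundle, "fiber_bundle"))
  if (bundle$provenance != "selected")
    stop("clean_outliers expects a selected bundle")
  if (length(bundle) < 5L) stop("need at least 5 fibers to clean")
  keep <- bundle
  removed <- 0L
  for (round in seq_len(max_rounds)) {
    cd <- bundle_core_distances(keep, n_nodes)
    lens <- vapply(keep$streamlines, streamline_length, 0)
    out <- rep(FALSE, length(keep))
    if (sd(cd) > 1e-12) out <- out | (cd > mean(cd) + core_sd * sd(cd))
    if (sd(lens) > 1e-12) out <- out | (lens > mean(lens) + len_sd * sd(lens))
    if (!any(out)) break
    if (all(out)) stop("degenerate bundle: cleaning removed every fiber")
    removed <- removed + sum(out)
    keep <- fiber_bundle(keep$streamlines[!out], "selected",
                         scores = keep$scores[!out],
                         creation_index = keep$creation_index[!out])
  }
  out <- fiber_bundle(keep$streamlines, "cleaned", scores = keep$scores,
                      creation_index = keep$creation_index)
  attr(out, "n_removed") <- removed
  out
}

# node-averaged Mahalanobis distance of each fiber to the node-wise core
bundle_core_distances <- function(bundle, n_nodes = 20L) {
  nf <- length(bundle)
  nodes <- array(NA_real_, c(nf, n_nodes, 3))
  for (i in seq_len(nf))
    nodes[i, , ] <- resample_equidistant(bundle$streamlines[[i]], n_nodes)
  dist <- matrix(0, nf, n_nodes)
  for (k in seq_len(n_nodes)) {
    x <- nodes[, k, ]
    mu <- colMeans(x)
    cv <- cov(x)
    ridge <- max(sum(diag(cv)), 1e-12) * 1e-8
    prec <- solve(cv + diag(ridge, 3))
    cen <- sweep(x, 2, mu)
    dist[, k] <- sqrt(pmax(rowSums((cen %*% prec) * cen), 0))
  }
  rowMeans(dist)
}

#' Resample a streamline to equidistant arc-length nodes
#'
#' @param s n x 3 point matrix with positive arc length.
#' @param n number of output nodes (>= 2); endpoints are preserved exactly.
#' @return n x 3 matrix of points at arc-length fractions 0, 1/(n-1), ..., 1.
#' @export
resample_equidistant <- function(s, n = 20L) {
  if (n < 2L) stop("n must be at least 2")
  total <- streamline_length(s)
  if (!(total > 0)) stop("streamline has zero arc length")
  out <- polyline_at(s, seq(0, total, length.out = n))
  out[1, ] <- s[1, ]; out[n, ] <- s[nrow(s), ]
  out
}

# ---- central fiber ---------------------------------------------------------

#' Extract the central fiber of a cleaned bundle
#'
#' Node-wise mean position over the cleaned, 20-node-resampled fibers.
#' Endpoints falling outside their ROI sphere are pulled radially onto the
#' sphere surface; the result is re-resampled to exactly 20 equidistant-arc
#' nodes with node 1 at the ONH (roi1) end.
#'
#' @param bundle a cleaned [fiber_bundle()].
#' @param roi1 ONH-end [roi_sphere()].
#' @param roi2 apex-end [roi_sphere()].
#' @param n_nodes number of nodes (default 20).
#' @return an object of class \code{central_fiber}: an n_nodes x 3 mm matrix.
#' @export
central_fiber <- function(bundle, roi1, roi2, n_nodes = 20L) {
  stopifnot(inherits(bundle, "fiber_bundle"))
  if (bundle$provenance != "cleaned")
    stop("central_fiber expects a cleaned bundle")
  if (length(bundle) < 1L) stop("empty bundle")
  nf <- length(bundle)
  acc <- matrix(0, n_nodes, 3)
  for (i in seq_len(nf))
    acc <- acc + resample_equidistant(bundle$streamlines[[i]], n_nodes)
  mean_path <- acc / nf
  # orient: node 1 at the ONH end
  if (sum((mean_path[1, ] - roi1$center)^2) >
      sum((mean_path[n_nodes, ] - roi1$center)^2))
    mean_path <- mean_path[n_nodes:1, ]
  mean_path[1, ] <- project_into_sphere(mean_path[1, ], roi1)
  mean_path[n_nodes, ] <- project_into_sphere(mean_path[n_nodes, ], roi2)
  out <- resample_equidistant(mean_path, n_nodes)
  structure(out, class = c("central_fiber", "matrix"))
}

project_into_sphere <- function(p, roi) {
  v <- p - roi$center
  r <- sqrt(sum(v^2))
  if (r <= roi$radius) p else roi$center + v * (roi$radius / r)
}

#' @export
print.central_fiber <- function(x, ...) {
  cat("<central_fiber> ", nrow(x), " nodes, arc length ",
      format(streamline_length(unclass(x)), digits = 4), " mm\n", sep = "")
  invisible(x)
}

# ---- streamline export -----------------------------------------------------

#' Write a fiber bundle as tidy CSV
#'
#' One row per (fiber, node): \code{fiber_id, node, x, y, z} in RAS+ mm.
#' @param bundle a [fiber_bundle()] or a [central_fiber()].
#' @param path output CSV path.
#' @param rois optional list of [roi_sphere()]s written to a JSON sidecar
#'   \code{<path stem>_rois.json}.
#' @return invisibly, the path.
#' @export
write_streamlines_csv <- function(bundle, path, rois = NULL) {
  sl <- if (inherits(bundle, "central_fiber")) list(unclass(bundle))
  else bundle$streamlines
  rows <- do.call(rbind, lapply(seq_along(sl), function(i)
    data.frame(fiber_id = i, node = seq_len(nrow(sl[[i]])),
               x = sl[[i]][, 1], y = sl[[i]][, 2], z = sl[[i]][, 3])))
  write.csv(rows, path, row.names = FALSE)
  if (!is.null(rois)) {
    jp <- sub("\\.csv$", "_rois.json", path)
    jsonlite::write_json(
      lapply(rois, function(r) list(center = r$center, radius = r$radius)),
      jp, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write streamlines in MRtrix TCK format
#'
#' Minimal TCK writer: text header, float32 little-endian triples, NaN track
#' separators, Inf terminator.  Geometry is RAS+ mm.
#' @param bundle a [fiber_bundle()] or [central_fiber()].
#' @param path output .tck path.
#' @return invisibly, the path.
#' @export
write_tck <- function(bundle, path) {
  sl <- if (inherits(bundle, "central_fiber")) list(unclass(bundle))
  else bundle$streamlines
  hdr <- c("mrtrix tracks", "datatype: Float32LE",
           paste0("count: ", length(sl)))
  # compute offset: header lines + "file: . <offset>" line + "END\n"
  base <- sum(nchar(hdr)) + length(hdr)   # with newlines
  guess <- base + 30L
  repeat {
    file_line <- paste0("file: . ", guess)
    total <- base + nchar(file_line) + 1L + 4L   # + "END\n"
    if (total <= guess) break
    guess <- guess + 1L
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, file_line, "END"), con, sep = "\n")
  pad <- guess - total
  if (pad > 0) writeBin(raw(pad), con)
  for (s in sl) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}
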