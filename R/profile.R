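# Sampling scalar maps along the central fiber and summarizing per nerve.

#' Sample a tract profile along a central fiber
#'
#' Each scalar map is interpolated at the mm position of every node
#' (trilinear by default; \code{"nearest"} reads the single voxel the node
#' falls in).  No node exclusion is applied at this stage.
#'
#' @param cf a [central_fiber()] (or any n x 3 mm node matrix).
#' @param maps a [scalar_maps()] object.
#' @param method \code{"trilinear"} or \code{"nearest"}.
#' @param nerve_id,subject_id,eye,group optional metadata carried through.
#' @return an object of class \code{tract_profile}: data frame with one row
#'   per node (node, x, y, z, fa, md, ad, rd, included).
#' @export
sample_profile <- function(cf, maps, method = c("trilinear", "nearest"),
                           nerve_id = NA, subject_id = NA, eye = NA,
                           group = NA) {
  method <- match.arg(method)
  stopifnot(inherits(maps, "scalar_maps"))
  pts <- rbind_point(unclass(cf))
  vox <- mm_to_vox(pts, maps$affine)
  d <- dim(maps$fa)
  bad <- which(vox[, 1] < 0 | vox[, 1] > d[1] - 1 |
                 vox[, 2] < 0 | vox[, 2] > d[2] - 1 |
                 vox[, 3] < 0 | vox[, 3] > d[3] - 1)
  if (length(bad))
    stop("node ", bad[1], " falls outside the image grid")
  interp <- if (method == "trilinear") interp_trilinear else interp_nearest
  prof <- data.frame(node = seq_len(nrow(pts)),
                     x = pts[, 1], y = pts[, 2], z = pts[, 3],
                     fa = interp(maps$fa, vox),
                     md = interp(maps$md, vox),
                     ad = interp(maps$ad, vox),
                     rd = interp(maps$rd, vox),
                     included = TRUE)
  attr(prof, "meta") <- list(nerve_id = nerve_id, subject_id = subject_id,
                             eye = eye, group = group)
  class(prof) <- c("tract_profile", "data.frame")
  prof
}

interp_nearest <- function(arr, vox) {
  d <- dim(arr)
  v <- round(vox)
  arr[cbind(v[, 1] + 1L, v[, 2] + 1L, v[, 3] + 1L)]
}

interp_trilinear <- function(arr, vox) {
  d <- dim(arr)
  lo <- floor(vox)
  lo[, 1] <- pmin(lo[, 1], d[1] - 2); lo[, 2] <- pmin(lo[, 2], d[2] - 2)
  lo[, 3] <- pmin(lo[, 3], d[3] - 2)
  lo <- pmax(lo, 0)
  f <- vox - lo
  out <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    out <- out + w * arr[cbind(lo[, 1] + 1L + dx, lo[, 2] + 1L + dy,
                               lo[, 3] + 1L + dz)]
  }
  out
}

#' Exclude the k nodes nearest the optic nerve head
#'
#' Masks nodes 1..k (node 1 is the ONH end), leaving the posterior
#' \code{n - k} nodes included; the default k = 5 of 20 nodes keeps the
#' posterior 75\%.
#'
#' @param p a [sample_profile()] result.
#' @param k number of anterior nodes to exclude (0 <= k < number of nodes).
#' @return the profile with its \code{included} mask updated.
#' @export
exclude_onh_nodes <- function(p, k = 5L) {
  stopifnot(inherits(p, "tract_profile"))
  n <- nrow(p)
  if (k < 0 || k >= n) stop("k must satisfy 0 <= k < ", n)
  p$included <- p$node > k
  p
}

#' Per-nerve summary of a tract profile
#'
#' Unweighted arithmetic mean of FA, MD, AD and RD over the included nodes.
#'
#' @param p a [tract_profile] (after any node exclusion).
#' @return object of class \code{nerve_summary}: list with fa, md, ad, rd and
#'   \code{n_nodes} used.
#' @export
summarize_profile <- function(p) {
  stopifnot(inherits(p, "tract_profile"))
  inc <- p$included
  if (!any(inc)) stop("no included nodes to summarize")
  out <- list(fa = mean(p$fa[inc]), md = mean(p$md[inc]),
              ad = mean(p$ad[inc]), rd = mean(p$rd[inc]),
              n_nodes = sum(inc), meta = attr(p, "meta"))
  class(out) <- "nerve_summary"
  out
}

#' @export
print.nerve_summary <- function(x, ...) {
  cat("<nerve_summary> over ", x$n_nodes, " nodes: FA ",
      format(x$fa, digits = 3), ", MD ", format(x$md, digits = 3),
      ", AD ", format(x$ad, digits = 3), ", RD ", format(x$rd, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Write tract profiles and nerve summaries as tidy CSV
#'
#' @param profiles list of [tract_profile] objects.
#' @param summaries list of [nerve_summary] objects.
#' @param profile_path,summary_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_profiles_csv <- function(profiles, summaries, profile_path,
                               summary_path) {
  prow <- do.call(rbind, lapply(profiles, function(p) {
    m <- attr(p, "meta")
    cbind(data.frame(nerve_id = m$nerve_id, subject_id = m$subject_id,
                     eye = m$eye, group = m$group), as.data.frame(p))
  }))
  write.csv(prow, profile_path, row.names = FALSE)
  srow <- do.call(rbind, lapply(summaries, function(s) {
    m <- s$meta
    data.frame(nerve_id = m$nerve_id, subject_id = m$subject_id, eye = m$eye,
               group = m$group, fa = s$fa, md = s$md, ad = s$ad, rd = s$rd,
               n_nodes = s$n_nodes)
  }))
  write.csv(srow, summary_path, row.names = FALSE)
  invisible(c(profile = profile_path, summary = summary_path))
}
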