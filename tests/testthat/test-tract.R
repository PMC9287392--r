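# Candidate generation, likelihood scoring, outlier cleaning, central fiber
# and equidistant resampling.

straight_track_setup <- function() {
  cached("straight_track", function() {
    ph <- make_phantom(straight_spec(snr = 20, seed = 13))
    tf <- fit_tensor_lls(merge_b0_pairs(ph$dwi))
    list(ph = ph, tf = tf)
  })
}

test_that("candidate generation is seeded, bounded and ROI-terminated", {
  su <- straight_track_setup()
  b1 <- generate_candidates(su$tf, su$ph$rois$onh, su$ph$rois$apex,
                            n = 150, seed = 5)
  b2 <- generate_candidates(su$tf, su$ph$rois$onh, su$ph$rois$apex,
                            n = 150, seed = 5)
  expect_length(b1, 150)
  expect_identical(b1$streamlines, b2$streamlines)
  expect_equal(b1$provenance, "candidates")

  straight <- sqrt(sum((su$ph$rois$apex$center - su$ph$rois$onh$center)^2))
  lens <- vapply(b1$streamlines, streamline_length, 0)
  # high-FA straight tube: lengths stay close to the straight-line distance
  expect_true(all(lens <= 2 * straight + 1e-9))
  expect_lt(median(abs(lens / straight - 1)), 0.10)

  for (s in b1$streamlines) {
    # oriented ONH -> apex and terminating inside the target sphere
    expect_lt(sqrt(sum((s[1, ] - su$ph$rois$onh$center)^2)),
              su$ph$rois$onh$radius + 1e-9)
    expect_lt(sqrt(sum((s[nrow(s), ] - su$ph$rois$apex$center)^2)),
              su$ph$rois$apex$radius + 1e-9)
  }

  expect_error(generate_candidates(su$tf, su$ph$rois$onh,
                                   roi_sphere(c(500, 500, 500), 3),
                                   n = 10, seed = 1),
               "outside the image grid")
})

test_that("scoring favours coherent in-tube fibers and selects the top fraction", {
  su <- straight_track_setup()
  bundle <- generate_candidates(su$tf, su$ph$rois$onh, su$ph$rois$apex,
                                n = 200, seed = 8)
  sel <- score_and_select(bundle, su$tf, keep_frac = 0.10)
  expect_length(sel, 20)
  expect_equal(sel$provenance, "selected")

  # count forced by ceiling(keep_frac * n), cross-checked by brute sort
  scores <- vapply(bundle$streamlines, ondti:::score_streamline, 0,
                   tf = su$tf, fa_vec = ondti:::tf_fa_vector(su$tf),
                   kappa0 = 100)
  expect_equal(sort(sel$scores, decreasing = TRUE),
               sort(scores, decreasing = TRUE)[1:20], tolerance = 1e-12)

  # keep_frac = 1 is the identity on membership
  all_sel <- score_and_select(bundle, su$tf, keep_frac = 1)
  expect_length(all_sel, 200)

  expect_error(score_and_select(bundle, su$tf, keep_frac = 0), "keep_frac")
  expect_error(score_and_select(sel, su$tf), "candidates")

  # a fiber pushed into isotropic background scores below an in-tube fiber
  tube <- sel$streamlines[[1]]
  detour <- tube
  mid <- seq(7, nrow(detour) - 6)
  detour[mid, 3] <- detour[mid, 3] + 10   # excursion off the tube in z
  fa_vec <- ondti:::tf_fa_vector(su$tf)
  expect_gt(ondti:::score_streamline(tube, su$tf, fa_vec, 100),
            ondti:::score_streamline(detour, su$tf, fa_vec, 100))

  # permutation invariance up to exact score ties
  perm <- sample(length(bundle))
  shuffled <- fiber_bundle(bundle$streamlines[perm], "candidates",
                           creation_index = bundle$creation_index[perm])
  sel2 <- score_and_select(shuffled, su$tf, keep_frac = 0.10)
  key <- function(b) sort(vapply(b$streamlines, function(s)
    sum(s[c(1, nrow(s)), ]), 0))
  expect_equal(key(sel2), key(sel), tolerance = 1e-9)
})

test_that("Watson sampler matches its analytic density moments", {
  set.seed(3)
  for (kap in c(0.5, 5, 25)) {
    t <- ondti:::rwatson_t(rep(kap, 20000))
    # oracle: E[t^2] by numerical integration of the density
    f <- function(x) exp(kap * x^2)
    m2 <- integrate(function(x) x^2 * f(x), -1, 1)$value /
      integrate(f, -1, 1)$value
    expect_equal(mean(t^2), m2, tolerance = 0.02)
  }
  # normalization constant against direct quadrature
  for (kap in c(0, 1, 17, 80))
    expect_equal(ondti:::log_watson_norm(kap),
                 log(2 * pi * integrate(function(x) exp(kap * x^2), -1, 1,
                                        rel.tol = 1e-12)$value),
                 tolerance = 1e-6)
})

test_that("outlier cleaning removes planted detours and is idempotent", {
  # synthetic bundle: 40 noisy copies of a straight line + 1 far detour
  set.seed(9)
  base <- cbind(10, seq(5, 35, length.out = 30), 10)
  mk <- function(jit) base + matrix(rnorm(90, sd = jit), ncol = 3)
  fibers <- lapply(1:40, function(i) mk(0.3))
  planted <- base; planted[10:20, 1] <- planted[10:20, 1] + 8
  fibers[[41]] <- planted
  bundle <- fiber_bundle(fibers, "selected")

  cleaned <- clean_outliers(bundle)
  expect_equal(cleaned$provenance, "cleaned")
  expect_gte(attr(cleaned, "n_removed"), 1L)
  # the planted fiber (creation index 41) is among the removed
  expect_false(41L %in% cleaned$creation_index)

  # brute-force check that the planted fiber exceeded the 2.6 SD threshold
  cd <- ondti:::bundle_core_distances(bundle)
  expect_gt(cd[41], mean(cd) + 2.6 * sd(cd))

  # idempotent once converged
  again <- clean_outliers(fiber_bundle(cleaned$streamlines, "selected",
                                       creation_index =
                                         cleaned$creation_index))
  expect_equal(attr(again, "n_removed"), 0L)
  expect_length(again, length(cleaned))

  # identical fibers: zero spread means nothing is removed
  same <- fiber_bundle(lapply(1:6, function(i) base), "selected")
  expect_equal(attr(clean_outliers(same), "n_removed"), 0L)

  expect_error(clean_outliers(fiber_bundle(fibers[1:4], "selected")),
               "at least 5")
})

test_that("length rule removes overlong fibers", {
  set.seed(2)
  base <- cbind(10, seq(5, 35, length.out = 30), 10)
  fibers <- lapply(1:30, function(i)
    base + matrix(rnorm(90, sd = 0.2), ncol = 3))
  # same corridor, but a wiggly (much longer) path
  long <- base
  long[, 1] <- long[, 1] + 1.2 * sin(seq(0, 14 * pi, length.out = 30))
  fibers[[31]] <- long
  lens <- vapply(fibers, streamline_length, 0)
  expect_gt(lens[31], mean(lens) + 3 * sd(lens))
  cleaned <- clean_outliers(fiber_bundle(fibers, "selected"))
  expect_false(31L %in% cleaned$creation_index)
})

test_that("resampling yields exact equidistant nodes and preserves endpoints", {
  line <- cbind(0, seq(0, 19, length.out = 7), 0)
  rs <- resample_equidistant(line, 20)
  expect_equal(nrow(rs), 20)
  steps <- sqrt(rowSums(diff(rs)^2))
  expect_equal(steps, rep(1, 19), tolerance = 1e-9)
  expect_equal(rs[1, ], line[1, ])
  expect_equal(rs[20, ], line[7, ])

  expect_equal(nrow(resample_equidistant(line, 2)), 2)
  expect_error(resample_equidistant(line, 1), "at least 2")

  # arc length of a smooth curve is preserved within 0.5% at n = 20
  t <- seq(0, pi, length.out = 400)
  curve <- cbind(10 * cos(t), 10 * sin(t), t)
  dense_len <- streamline_length(curve)
  rs20 <- resample_equidistant(curve, 20)
  expect_equal(streamline_length(rs20), dense_len, tolerance = 0.005)
})

test_that("central fiber averages the bundle and respects ROI and orientation", {
  base <- cbind(10, seq(5, 35, length.out = 25), 10)
  roi1 <- roi_sphere(base[1, ], 3); roi2 <- roi_sphere(base[25, ], 3)

  # identical fibers: central fiber equals any member
  same <- fiber_bundle(lapply(1:5, function(i) base), "cleaned")
  cf <- central_fiber(same, roi1, roi2)
  expect_equal(unclass(cf), resample_equidistant(base, 20),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(nrow(cf), 20)

  # two symmetric fibers: central fiber on the axis
  off <- base; off[, 1] <- off[, 1] + 1.5
  off2 <- base; off2[, 1] <- off2[, 1] - 1.5
  sym <- fiber_bundle(list(off, off2), "cleaned")
  cf2 <- central_fiber(sym, roi1, roi2)
  expect_equal(unname(cf2[, 1]), rep(10, 20), tolerance = 1e-9)

  # node 1 is the ONH end for every run
  expect_lt(sqrt(sum((cf2[1, ] - roi1$center)^2)),
            sqrt(sum((cf2[20, ] - roi1$center)^2)))

  # endpoints outside the ROI are pulled onto the sphere
  shifted <- base; shifted[1, 2] <- shifted[1, 2] - 8
  bun <- fiber_bundle(list(shifted), "cleaned")
  cf3 <- central_fiber(bun, roi1, roi2)
  expect_lte(sqrt(sum((cf3[1, ] - roi1$center)^2)), roi1$radius + 1e-6)

  expect_error(central_fiber(same, roi1, roi2, n_nodes = 20)[21, ])
})

test_that("central fiber tracks the true centerline within one voxel", {
  su <- straight_track_setup()
  res <- run_nerve_pipeline(su$ph$dwi, su$ph$rois$onh, su$ph$rois$apex,
                            pipeline_config(n_candidates = 400, seed = 3))
  cf <- res$central_fiber
  cl <- su$ph$centerline
  d <- vapply(seq_len(nrow(cf)), function(i)
    min(sqrt(rowSums(sweep(cl, 2, cf[i, ])^2))), 0)
  expect_lt(max(d), 2.0)
})

test_that("central fiber stays sub-voxel accurate across keep fractions", {
  # candidates are ROI-terminated, so the bundle is already confined to the
  # tube; the central fiber must remain within half a voxel of the truth for
  # any keep fraction (selection trades averaging noise, not outlier mass)
  rms_at <- function(keep, seeds) {
    mean(vapply(seeds, function(s) {
      ph <- make_phantom(straight_spec(snr = 20, seed = s))
      tf <- fit_tensor_lls(merge_b0_pairs(ph$dwi))
      cand <- generate_candidates(tf, ph$rois$onh, ph$rois$apex, n = 200,
                                  seed = s + 100)
      sel <- score_and_select(cand, tf, keep_frac = keep)
      cl <- tryCatch(clean_outliers(sel), error = function(e) sel)
      cf <- central_fiber(
        if (cl$provenance == "cleaned") cl else
          fiber_bundle(cl$streamlines, "cleaned"),
        ph$rois$onh, ph$rois$apex)
      truth <- ph$centerline
      sqrt(mean(vapply(seq_len(nrow(cf)), function(i)
        min(rowSums(sweep(truth, 2, cf[i, ])^2)), 0)))
    }, 0))
  }
  seeds <- 1:3
  expect_lt(rms_at(0.10, seeds), 1.0)
  expect_lt(rms_at(1.0, seeds), 1.0)
})

test_that("streamline CSV and TCK writers round-trip geometry", {
  base <- cbind(10, seq(5, 35, length.out = 12), 10)
  bun <- fiber_bundle(list(base, base + 0.5), "cleaned")
  td <- withr::local_tempdir()
  csv <- file.path(td, "fibers.csv")
  write_streamlines_csv(bun, csv, rois = list(onh = roi_sphere(base[1, ], 3)))
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 24)
  expect_equal(tab$x[tab$fiber_id == 2][1], 10.5)
  expect_true(file.exists(file.path(td, "fibers_rois.json")))

  tck <- file.path(td, "fibers.tck")
  write_tck(bun, tck)
  con <- file(tck, "rb")
  hdr <- readLines(con, n = 5)
  expect_equal(hdr[1], "mrtrix tracks")
  offset <- as.integer(sub("file: . ", "", hdr[4], fixed = TRUE))
  close(con)
  con <- file(tck, "rb")
  seek(con, offset)
  floats <- readBin(con, "numeric", n = (12 * 2 + 3) * 3, size = 4,
                    endian = "little")
  close(con)
  expect_equal(floats[1:3], base[1, ], tolerance = 1e-6)
  expect_true(all(is.nan(floats[37:39])))   # track separator after fiber 1
})
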