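# Orchestration: per-nerve pipeline (b0 merge -> tensor fit -> tractography
# -> cleaning -> central fiber -> profile -> summary) and the cohort loop.

#' Pipeline configuration
#'
#' Validated container for every tunable stage parameter.  Unknown fields
#' are rejected.  Defaults follow the clinical acquisition and analysis
#' protocol: 48 directions at b = 2000 s/mm^2, 2 mm isotropic voxels,
#' 1000 candidates with the top 10\% kept, 2.6 SD core / 3 SD length
#' cleaning, 20 nodes with the 5 nearest the ONH excluded, 500 bootstrap
#' replicates.
#'
#' @param ... named overrides of the defaults (see
#'   \code{names(pipeline_config())}).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(n_dirs = 48L, b = 2000, voxel = 2.0, snr = 20,
              n_candidates = 1000L, keep_frac = 0.10, core_sd = 2.6,
              len_sd = 3.0, step_mm = 1.0, max_angle = 45, kappa0 = 100,
              n_nodes = 20L, exclude_k = 5L, n_boot = 500L,
              interp = "trilinear", seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot(n_dirs >= 6, b > 0, voxel > 0, snr > 0,
              n_candidates >= 1, keep_frac > 0, keep_frac <= 1,
              core_sd > 0, len_sd > 0, step_mm > 0,
              max_angle > 0, max_angle <= 90, kappa0 >= 0,
              n_nodes >= 2, exclude_k >= 0, exclude_k < n_nodes,
              n_boot >= 2, interp %in% c("trilinear", "nearest"))
  })
  structure(cfg, class = "pipeline_config")
}

#' Run the full per-nerve pipeline on a diffusion dataset
#'
#' Merges the opposed-phase b0 pair, fits tensors by log-linear least
#' squares, generates and scores candidate streamlines between the two ROIs,
#' cleans outliers, extracts the central fiber, samples the 20-node tract
#' profile, excludes the ONH-nearest nodes and averages the rest.
#'
#' @param ds a [dwi_dataset()] (with AP/PA-tagged b0 volumes).
#' @param roi1,roi2 [roi_sphere()]s at the ONH and orbital-apex ends.
#' @param config a [pipeline_config()].
#' @param meta optional list(nerve_id, subject_id, eye, group).
#' @return list with \code{summary} ([summarize_profile()] result),
#'   \code{profile}, \code{central_fiber}, \code{maps}, \code{tensors} and a
#'   \code{log} of per-stage counts.
#' @export
run_nerve_pipeline <- function(ds, roi1, roi2, config = pipeline_config(),
                               meta = list()) {
  stopifnot(inherits(config, "pipeline_config"))
  merged <- merge_b0_pairs(ds)
  tf <- fit_tensor_lls(merged)
  maps <- scalar_maps(tf)
  cand <- generate_candidates(tf, roi1, roi2, n = config$n_candidates,
                              seed = config$seed, step_mm = config$step_mm,
                              max_angle_deg = config$max_angle,
                              kappa0 = config$kappa0)
  # when far fewer candidates than requested were accepted, keep at least
  # the 5 fibers the core statistics of the cleaning stage need
  keep_frac <- max(config$keep_frac, min(1, 5 / length(cand)))
  sel <- score_and_select(cand, tf, keep_frac = keep_frac,
                          kappa0 = config$kappa0)
  cleaned <- clean_outliers(sel, core_sd = config$core_sd,
                            len_sd = config$len_sd,
                            n_nodes = config$n_nodes)
  cf <- central_fiber(cleaned, roi1, roi2, n_nodes = config$n_nodes)
  prof <- sample_profile(cf, maps, method = config$interp,
                         nerve_id = meta$nerve_id %||% NA,
                         subject_id = meta$subject_id %||% NA,
                         eye = meta$eye %||% NA, group = meta$group %||% NA)
  prof <- exclude_onh_nodes(prof, k = config$exclude_k)
  summ <- summarize_profile(prof)
  list(summary = summ, profile = prof, central_fiber = cf, maps = maps,
       tensors = tf,
       log = list(n_volumes_merged = dim(merged$signal)[4],
                  n_candidates = length(cand),
                  n_attempted = attr(cand, "n_attempted"),
                  n_selected = length(sel),
                  n_removed = attr(cleaned, "n_removed"),
                  n_cleaned = length(cleaned),
                  n_nodes = nrow(prof),
                  n_included = sum(prof$included)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the pipeline over a synthetic cohort
#'
#' Simulates each nerve phantom (lazily, one at a time), runs
#' [run_nerve_pipeline()] with per-nerve ROIs derived from the phantom
#' centerline, and assembles the measured cohort table.
#'
#' @param cohort a [make_cohort()] result.
#' @param config a [pipeline_config()].
#' @param progress print one line per nerve.
#' @return list with \code{table} (measured cohort: subject_id, eye, group,
#'   rnfl_um, fa, md, ad, rd plus the ground-truth columns) and
#'   \code{results} (per-nerve pipeline outputs without the heavy maps).
#' @export
run_cohort_pipeline <- function(cohort, config = pipeline_config(),
                                progress = FALSE) {
  rows <- list(); results <- list()
  for (i in seq_along(cohort$nerves)) {
    nv <- cohort$nerves[[i]]
    if (is.null(nv$dwi)) {
      ph <- make_phantom(nv$spec)
      nv$dwi <- ph$dwi; nv$rois <- ph$rois
    }
    cfg_i <- config
    cfg_i$seed <- (nv$seed + 1L) %% .Machine$integer.max
    res <- tryCatch(
      run_nerve_pipeline(nv$dwi, nv$rois$onh, nv$rois$apex, cfg_i,
                         meta = list(nerve_id = i,
                                     subject_id = nv$subject_id,
                                     eye = nv$eye, group = nv$group)),
      error = function(e) {
        warning("nerve ", i, " (", nv$subject_id, " ", nv$eye,
                ") failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) {
      rows[[i]] <- data.frame(subject_id = nv$subject_id, eye = nv$eye,
                              group = nv$group, rnfl_um = nv$rnfl_um,
                              fa = NA_real_, md = NA_real_, ad = NA_real_,
                              rd = NA_real_, fa_truth = nv$fa_truth,
                              ad_truth = nv$ad_truth, rd_truth = nv$rd_truth,
                              md_truth = nv$md_truth)
      results[[i]] <- list(failed = TRUE)
      next
    }
    s <- res$summary
    rows[[i]] <- data.frame(subject_id = nv$subject_id, eye = nv$eye,
                            group = nv$group, rnfl_um = nv$rnfl_um,
                            fa = s$fa, md = s$md, ad = s$ad, rd = s$rd,
                            fa_truth = nv$fa_truth, ad_truth = nv$ad_truth,
                            rd_truth = nv$rd_truth, md_truth = nv$md_truth)
    results[[i]] <- list(summary = res$summary, profile = res$profile,
                         central_fiber = res$central_fiber, log = res$log)
    if (progress)
      message(sprintf("nerve %d/%d (%s %s %s): FA %.3f", i,
                      length(cohort$nerves), nv$subject_id, nv$eye,
                      nv$group, s$fa))
  }
  list(table = do.call(rbind, rows), results = results)
}
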