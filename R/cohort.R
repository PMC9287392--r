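# Cohort-level synthetic data: per-nerve diffusivity profiles with
# subject-structured jitter, and RNFL thickness linked linearly to the
# nerve's ground-truth FA.

#' Default group diffusivity profiles and their spreads
#'
#' Published group means and standard deviations of the four tensor measures
#' for atrophic, non-affected and control optic nerves, on the printed scale.
#' The cohort generator uses the AD/RD rows as its group profiles.
#'
#' @return data frame with columns group, measure, mean, sd.
#' @export
reference_group_measures <- function() {
  data.frame(
    group = rep(c("atrophic", "non_affected", "control"), each = 4),
    measure = rep(c("fa", "md", "ad", "rd"), 3),
    mean = c(0.136, 0.988, 1.123, 0.920,
             0.384, 0.658, 0.955, 0.510,
             0.389, 0.687, 0.998, 0.532),
    sd = c(0.059, 0.247, 0.252, 0.247,
           0.048, 0.058, 0.080, 0.054,
           0.053, 0.079, 0.094, 0.078))
}

#' Reference per-case RNFL thickness of the unilateral optic-atrophy cohort
#'
#' Peripapillary RNFL thickness (micrometres) of the affected and
#' non-affected eye of the six patients, shipped as a plain-text fixture.
#'
#' @return data frame with columns case, affected_rnfl_um,
#'   nonaffected_rnfl_um.
#' @export
reference_rnfl_table <- function() {
  read.csv(system.file("extdata", "oa_cohort_rnfl.csv", package = "ondti",
                       mustWork = TRUE))
}

#' Specification of a synthetic cohort
#'
#' Six patients (one atrophic + one non-affected nerve each) and eleven
#' controls (two control nerves each) by default.  Per-nerve AD/RD are the
#' group profile plus between-subject Gaussian jitter (shared by a subject's
#' nerves of the same group); RNFL is a linear function of the nerve's
#' ground-truth FA plus noise.  Defaults for the profiles and jitter SDs are
#' the published group means/SDs; the RNFL link (intercept 22, slope 236,
#' noise SD 8 um) reproduces the published group RNFL means at the
#' profile-implied FA values.
#'
#' @param n_patients,n_controls subject counts.
#' @param profiles named list of c(ad, rd) per group.
#' @param jitter_sd named list of c(ad, rd) marginal jitter SDs per group;
#'   the AD/RD jitter is drawn bivariate-normal with the correlation that
#'   makes the implied FA spread match \code{fa_sd} (delta method).
#' @param fa_sd named numeric of target FA SDs per group.
#' @param rnfl_model list(intercept, slope, noise_sd) mapping FA to RNFL um.
#' @param phantom a [phantom_spec()] template used for every nerve (its
#'   nerve_ad/nerve_rd are overridden per nerve).
#' @param seed integer master seed.
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_patients = 6L, n_controls = 11L,
                        profiles = list(atrophic = c(ad = 1.123, rd = 0.920),
                                        non_affected = c(ad = 0.955, rd = 0.510),
                                        control = c(ad = 0.998, rd = 0.532)),
                        jitter_sd = list(atrophic = c(ad = 0.252, rd = 0.247),
                                         non_affected = c(ad = 0.080, rd = 0.054),
                                         control = c(ad = 0.094, rd = 0.078)),
                        fa_sd = c(atrophic = 0.059, non_affected = 0.048,
                                  control = 0.053),
                        rnfl_model = list(intercept = 22, slope = 236,
                                          noise_sd = 8),
                        phantom = phantom_spec(), seed = 1L) {
  if (n_patients < 1L || n_controls < 1L)
    stop("need at least one patient and one control")
  if (rnfl_model$noise_sd < 0) stop("rnfl noise SD must be >= 0")
  stopifnot(all(c("atrophic", "non_affected", "control") %in% names(profiles)))
  rho <- vapply(names(profiles), function(g)
    jitter_correlation(profiles[[g]], jitter_sd[[g]], fa_sd[[g]]), 0)
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 profiles = profiles, jitter_sd = jitter_sd,
                 fa_sd = fa_sd, jitter_rho = rho,
                 rnfl_model = rnfl_model, phantom = phantom,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# AD/RD jitter correlation that makes the FA spread implied by the marginal
# AD/RD SDs match the published FA SD (delta method at the group profile).
# Published per-measure SDs are marginals of strongly correlated quantities:
# independent AD/RD jitter would give FA spreads several times the published
# ones (and heavy truncation at AD >= RD).
jitter_correlation <- function(profile, jsd, fa_sd) {
  a <- profile[["ad"]]; r <- profile[["rd"]]
  s <- sqrt(a^2 + 2 * r^2)
  ga <- 1 / s - (a - r) * a / s^3        # dFA/dAD
  gr <- -1 / s - (a - r) * 2 * r / s^3   # dFA/dRD (negative)
  num <- ga^2 * jsd[["ad"]]^2 + gr^2 * jsd[["rd"]]^2 - fa_sd^2
  den <- -2 * ga * gr * jsd[["ad"]] * jsd[["rd"]]
  min(max(num / den, -0.99), 0.99)
}

# one AD/RD draw: group profile + correlated bivariate jitter, resampled
# until AD >= RD > 0 (rare under the fitted correlation)
draw_profile <- function(profile, jsd, rho, max_try = 100L) {
  for (i in seq_len(max_try)) {
    z1 <- rnorm(1); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1)
    ad <- profile[["ad"]] + jsd[["ad"]] * z1
    rd <- profile[["rd"]] + jsd[["rd"]] * z2
    if (ad >= rd && rd > 0) return(c(ad = ad, rd = rd))
  }
  c(ad = max(profile[["ad"]], profile[["rd"]] + 1e-3),
    rd = max(profile[["rd"]], 1e-3))
}

#' Generate a synthetic cohort
#'
#' Each patient receives one atrophic-profile and one non-affected-profile
#' nerve (right/left eye), each control two control-profile nerves sharing
#' the subject's jitter draw.  Per nerve the record carries its ground-truth
#' diffusivities, FA, RNFL and a derived simulation seed; with
#' \code{simulate = TRUE} the DWI volumes are materialized immediately
#' (memory permitting), otherwise the pipeline simulates them lazily.
#'
#' @param cspec a [cohort_spec()].
#' @param simulate materialize the DWI of every nerve now.
#' @return list with \code{nerves} (list of per-nerve records) and
#'   \code{table} (the cohort ground-truth skeleton: subject_id, eye, group,
#'   rnfl_um, fa_truth, ad_truth, rd_truth, md_truth).
#' @export
make_cohort <- function(cspec, simulate = FALSE) {
  stopifnot(inherits(cspec, "cohort_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cspec$seed)

  rows <- list(); nerves <- list()
  add_nerve <- function(subject_id, eye, group, adrd) {
    fa <- fa_axial(adrd[["ad"]], adrd[["rd"]])
    rnfl <- cspec$rnfl_model$intercept + cspec$rnfl_model$slope * fa +
      rnorm(1, sd = cspec$rnfl_model$noise_sd)
    sim_seed <- sample.int(.Machine$integer.max, 1L)
    spec <- cspec$phantom
    spec$nerve_ad <- adrd[["ad"]]; spec$nerve_rd <- adrd[["rd"]]
    spec$seed <- sim_seed
    rec <- list(subject_id = subject_id, eye = eye, group = group,
                ad_truth = adrd[["ad"]], rd_truth = adrd[["rd"]],
                md_truth = (adrd[["ad"]] + 2 * adrd[["rd"]]) / 3,
                fa_truth = fa, rnfl_um = rnfl, seed = sim_seed, spec = spec)
    nerves[[length(nerves) + 1L]] <<- rec
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = subject_id, eye = eye, group = group, rnfl_um = rnfl,
      fa_truth = fa, ad_truth = adrd[["ad"]], rd_truth = adrd[["rd"]],
      md_truth = rec$md_truth)
  }
  for (p in seq_len(cspec$n_patients)) {
    sid <- sprintf("P%02d", p)
    add_nerve(sid, "right", "atrophic",
              draw_profile(cspec$profiles$atrophic, cspec$jitter_sd$atrophic,
                           cspec$jitter_rho[["atrophic"]]))
    add_nerve(sid, "left", "non_affected",
              draw_profile(cspec$profiles$non_affected,
                           cspec$jitter_sd$non_affected,
                           cspec$jitter_rho[["non_affected"]]))
  }
  for (cc in seq_len(cspec$n_controls)) {
    sid <- sprintf("C%02d", cc)
    adrd <- draw_profile(cspec$profiles$control, cspec$jitter_sd$control,
                         cspec$jitter_rho[["control"]])
    add_nerve(sid, "right", "control", adrd)
    add_nerve(sid, "left", "control", adrd)
  }
  if (simulate)
    for (i in seq_along(nerves)) {
      ph <- make_phantom(nerves[[i]]$spec)
      nerves[[i]]$dwi <- ph$dwi
      nerves[[i]]$rois <- ph$rois
      nerves[[i]]$centerline <- ph$centerline
    }
  list(nerves = nerves, table = do.call(rbind, rows))
}

#' Analytic R-squared of the cohort's FA-RNFL link
#'
#' Variance decomposition of \code{rnfl = intercept + slope * FA + noise}
#' over the realized ground-truth FA values of the supplied rows:
#' \code{slope^2 Var(FA) / (slope^2 Var(FA) + noise_sd^2)}.
#'
#' @param table cohort skeleton rows (with \code{fa_truth}).
#' @param rnfl_model the generator's link, as in [cohort_spec()].
#' @return R-squared in [0, 1].
#' @export
analytic_rnfl_r2 <- function(table, rnfl_model) {
  s2 <- rnfl_model$slope^2 * var(table$fa_truth)
  s2 / (s2 + rnfl_model$noise_sd^2)
}
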