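# Cohort statistics: inter-eye averaging for controls, nonparametric
# demographics tests, and linear mixed-effects association of diffusion
# measures with RNFL thickness or group.

#' Average the two eyes of every control subject
#'
#' Control rows are replaced by one per-subject row carrying the mean of
#' each diffusion measure and of RNFL; patient rows pass through untouched.
#'
#' @param tab cohort data frame with columns subject_id, group, eye, rnfl_um
#'   and any of fa, md, ad, rd.
#' @return data frame with one row per control subject and the original
#'   patient rows.
#' @export
average_control_eyes <- function(tab) {
  need <- c("subject_id", "group", "eye", "rnfl_um")
  if (!all(need %in% names(tab)))
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  ctrl <- tab[tab$group == "control", , drop = FALSE]
  pat <- tab[tab$group != "control", , drop = FALSE]
  if (nrow(ctrl)) {
    cnt <- table(ctrl$subject_id)
    if (any(cnt != 2L))
      stop("every control subject must contribute exactly 2 eye rows")
    meas <- intersect(c("rnfl_um", "fa", "md", "ad", "rd",
                        "fa_truth", "ad_truth", "rd_truth", "md_truth"),
                      names(ctrl))
    agg <- aggregate(ctrl[meas], by = list(subject_id = ctrl$subject_id),
                     FUN = mean)
    agg$group <- "control"
    agg$eye <- "both"
    ctrl <- agg[, c("subject_id", "group", "eye", meas)]
  }
  common <- intersect(names(pat), names(ctrl))
  rbind(pat[common], ctrl[common])
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with midrank ties.  The p-value is exact (full
#' permutation distribution) when both samples have at most
#' \code{exact_threshold} observations and there are no ties; otherwise the
#' normal approximation with tie and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_threshold maximum per-sample size for the exact p.
#' @return list with \code{U} (statistic for x), \code{p} (two-sided) and
#'   \code{method}.
#' @export
mann_whitney_u <- function(x, y, exact_threshold = 25L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- any(duplicated(c(x, y)))
  use_exact <- length(x) <= exact_threshold && length(y) <= exact_threshold &&
    !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE))
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  list(U = U, p = unname(wt$p.value),
       method = if (use_exact) "exact" else "normal approximation")
}

#' Pearson chi-square test on a 2x2 proportion table
#'
#' Without continuity correction, df = 1.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return list with \code{chisq}, \code{p} and \code{df}.
#' @export
chi_square_prop <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2L, 2L)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in the contingency table")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(chisq = unname(ct$statistic), p = unname(ct$p.value), df = 1L)
}

lmer_relaxed_control <- function()
  lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.rankZ = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    calc.derivs = FALSE)

lme_result <- function(model, data, measure, predictor) {
  fe <- lme4::fixef(model)
  vc <- as.data.frame(lme4::VarCorr(model))
  var_random <- vc$vcov[vc$grp == "subject_id"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  X <- stats::model.matrix(model)
  fitted_fixed <- as.numeric(X %*% fe)
  y <- data[[measure]]
  r2 <- if (sd(fitted_fixed) > 0) cor(fitted_fixed, y)^2 else 0
  an <- suppressMessages(anova(model))
  p <- an[predictor, "Pr(>F)"]
  structure(list(fixed = fe, var_random = var_random, var_resid = var_resid,
                 r2 = r2, p = unname(p), anova = an, measure = measure,
                 predictor = predictor, n = nrow(data), model = model),
            class = "lme_result")
}

#' @export
print.lme_result <- function(x, ...) {
  cat("<lme_result> ", x$measure, " ~ ", x$predictor,
      " + (1|subject): slope ", format(x$fixed[2], digits = 4),
      ", R2 ", format(x$r2, digits = 3),
      ", p ", format.pval(x$p, digits = 3), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Mixed-effects association of a diffusion measure with RNFL thickness
#'
#' Fits \code{measure ~ rnfl_um + (1 | subject_id)} by REML; the p-value
#' comes from the Satterthwaite ANOVA of the fixed effect and R-squared is
#' the squared Pearson correlation between the fixed-effect fitted values
#' and the observations.  With one observation per subject the random
#' intercept is unidentifiable, its variance is pinned at the zero boundary
#' and the estimates coincide with ordinary least squares.
#'
#' @param tab cohort rows to use (e.g. both eyes of every patient).
#' @param measure one of \code{"fa"}, \code{"md"}, \code{"ad"}, \code{"rd"}.
#' @return an \code{lme_result}.
#' @export
fit_lme_rnfl <- function(tab, measure = c("fa", "md", "ad", "rd")) {
  measure <- match.arg(measure)
  if (length(unique(tab$subject_id)) < 4L)
    stop("need at least 4 subjects")
  if (sd(tab$rnfl_um) == 0) stop("constant RNFL: singular design")
  f <- as.formula(paste(measure, "~ rnfl_um + (1 | subject_id)"))
  m <- suppressWarnings(suppressMessages(
    lmerTest::lmer(f, data = tab, REML = TRUE,
                   control = lmer_relaxed_control())))
  lme_result(m, tab, measure, "rnfl_um")
}

#' Mixed-effects group contrast of a diffusion measure
#'
#' Fits \code{measure ~ group + (1 | subject_id)} by REML on the rows of the
#' two groups involved in the contrast (atrophic vs control uses the
#' atrophic nerves and the eye-averaged controls; atrophic vs non-affected
#' uses both eyes of every patient).
#'
#' @param tab cohort table (after [average_control_eyes()] for contrasts
#'   involving controls).
#' @param measure one of \code{"fa"}, \code{"md"}, \code{"ad"}, \code{"rd"}.
#' @param contrast \code{"atrophic_vs_control"} or
#'   \code{"atrophic_vs_nonaffected"}.
#' @return an \code{lme_result}; \code{fixed[2]} is the non-atrophic minus
#'   atrophic difference.
#' @export
fit_lme_group <- function(tab, measure = c("fa", "md", "ad", "rd"),
                          contrast = c("atrophic_vs_control",
                                       "atrophic_vs_nonaffected")) {
  measure <- match.arg(measure)
  contrast <- match.arg(contrast)
  other <- if (contrast == "atrophic_vs_control") "control" else "non_affected"
  sub <- tab[tab$group %in% c("atrophic", other), , drop = FALSE]
  if (!all(c("atrophic", other) %in% sub$group))
    stop("both groups of the contrast must be present")
  sub$group <- factor(sub$group, levels = c("atrophic", other))
  f <- as.formula(paste(measure, "~ group + (1 | subject_id)"))
  m <- suppressWarnings(suppressMessages(
    lmerTest::lmer(f, data = sub, REML = TRUE,
                   control = lmer_relaxed_control())))
  lme_result(m, sub, measure, "group")
}

#' Full statistical report for a measured cohort
#'
#' Group means +/- SD of the four measures and RNFL, the control inter-eye
#' Mann-Whitney checks, the group LME contrasts and the RNFL LME
#' associations, mirroring the structure of a clinical DTI results section.
#'
#' @param tab measured cohort table (one row per nerve: subject_id, group,
#'   eye, rnfl_um, fa, md, ad, rd).
#' @return a list of class \code{cohort_report}.
#' @export
cohort_report <- function(tab) {
  measures <- c("fa", "md", "ad", "rd")
  grp_stats <- do.call(rbind, lapply(measures, function(m)
    do.call(rbind, lapply(split(tab[[m]], tab$group), function(v)
      data.frame(measure = m, mean = mean(v), sd = sd(v))))))
  grp_stats$group <- sub("\\.\\d+$", "", rownames(grp_stats))
  rownames(grp_stats) <- NULL

  inter_eye <- NULL
  ctrl <- tab[tab$group == "control", ]
  if (nrow(ctrl) && all(table(ctrl$subject_id) == 2L)) {
    inter_eye <- vapply(c(measures, "rnfl_um"), function(m) {
      wide <- split(ctrl[[m]], ctrl$eye)
      mann_whitney_u(wide[[1]], wide[[2]])$p
    }, 0)
  }

  avg <- average_control_eyes(tab)
  contrasts <- list()
  for (m in measures)
    for (ct in c("atrophic_vs_control", "atrophic_vs_nonaffected")) {
      src <- if (ct == "atrophic_vs_control") avg else tab
      contrasts[[paste(m, ct, sep = ".")]] <-
        tryCatch(fit_lme_group(src, m, ct), error = function(e) NULL)
    }

  pats <- tab[tab$group %in% c("atrophic", "non_affected"), ]
  rnfl_assoc <- lapply(setNames(measures, measures), function(m)
    tryCatch(fit_lme_rnfl(pats, m), error = function(e) NULL))

  structure(list(group_stats = grp_stats, inter_eye_p = inter_eye,
                 group_contrasts = contrasts, rnfl_association = rnfl_assoc,
                 n_nerves = nrow(tab)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> ", x$n_nerves, " nerves\n\nGroup means +/- SD:\n",
      sep = "")
  print(x$group_stats, digits = 3)
  cat("\nRNFL association (patients, both eyes):\n")
  for (m in names(x$rnfl_association)) {
    r <- x$rnfl_association[[m]]
    if (!is.null(r))
      cat(sprintf("  %s: R2 = %.3f, p = %s\n", m, r$r2,
                  format.pval(r$p, digits = 3)))
  }
  cat("\nGroup contrasts:\n")
  for (nm in names(x$group_contrasts)) {
    r <- x$group_contrasts[[nm]]
    if (!is.null(r))
      cat(sprintf("  %s: diff = %.3f, p = %s\n", nm, -r$fixed[2],
                  format.pval(r$p, digits = 3)))
  }
  invisible(x)
}
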