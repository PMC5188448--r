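# Repeated-measures analysis of BMI: does the genotype effect on BMI
# trajectories differ by baseline T2D status?

#' Build a complete-case longitudinal BMI panel
#'
#' Joins a long repeated-measures BMI table (subject_id, visit_year,
#' bmi) to cohort baseline data and keeps only subjects with a BMI
#' measurement at every visit of the chosen window (baseline through
#' year 4 or year 6), mirroring the complete-data requirement of
#' repeated-measures ANCOVA.
#'
#' @param cohort a `grs_cohort`.
#' @param bmi_long data.frame with columns `subject_id`, `visit_year`
#'   (integer, 0 = baseline), `bmi`.
#' @param window follow-up window in years: 4 or 6.
#' @param snp SNP id whose genotype is attached to the panel.
#' @return data.frame of class `long_panel` (one row per subject x
#'   visit) with genotype codes, T2D status and baseline covariates;
#'   attribute `retention` records input and retained subject counts.
#' @export
build_panel <- function(cohort, bmi_long, window = c(4, 6),
                        snp = "rs7903146") {
  window <- match.arg(as.character(window[1]), c("4", "6"))
  window <- as.integer(window)
  needed <- c("subject_id", "visit_year", "bmi")
  missing <- setdiff(needed, names(bmi_long))
  if (length(missing))
    stop("BMI table is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(bmi_long[, c("subject_id", "visit_year")]))
    stop("duplicate (subject, visit) rows in the BMI table")

  visits <- 0:window
  sub <- bmi_long[bmi_long$visit_year %in% visits & !is.na(bmi_long$bmi), ]
  counts <- table(sub$subject_id)
  complete_ids <- names(counts)[counts == length(visits)]
  complete_ids <- intersect(complete_ids, cohort$subject_id)

  ann <- snp_annotation_row(attr(cohort, "annotation"), snp)
  base <- as.data.frame(cohort)
  base$g_add <- code_genotype(base[[geno_col(snp)]], ann, "additive")
  base_cols <- c("subject_id", "g_add", "t2d_prevalent", "sex", "age",
                 "center", "arm",
                 intersect(.COVARIATE_COLS, names(base)))
  base <- base[base$subject_id %in% complete_ids, base_cols, drop = FALSE]
  base <- base[!is.na(base$g_add), , drop = FALSE]

  panel <- merge(sub[sub$subject_id %in% base$subject_id, needed], base,
                 by = "subject_id")
  panel <- panel[order(panel$subject_id, panel$visit_year), ]
  rownames(panel) <- NULL
  structure(panel,
            retention = list(n_subjects_in = length(unique(bmi_long$subject_id)),
                             n_subjects_kept = length(unique(panel$subject_id)),
                             window = window),
            class = c("long_panel", "data.frame"))
}

#' Repeated-measures model of BMI trajectories
#'
#' Fits a linear mixed model with a subject-level random intercept
#' (compound-symmetry covariance, the modern analogue of
#' repeated-measures ANCOVA) of BMI on genotype, T2D status, their
#' interaction, visit and optional baseline covariates.  The
#' between-subject genotype effect and the genotype x T2D interaction
#' are tested by Type-III-style F tests with Satterthwaite degrees of
#' freedom; adjusted genotype x T2D x visit means are obtained by
#' marginal standardisation over the observed covariates.
#'
#' @param panel a `long_panel` from [build_panel()].
#' @param covariates character vector of baseline covariate columns to
#'   adjust for (may be empty).
#' @return list with `p_genotype` (between-subject effect),
#'   `p_interaction` (genotype x T2D), `adjusted_means` (data.frame:
#'   t2d, genotype code, visit_year, mean) and the fitted `model`.
#' @export
fit_repeated_bmi <- function(panel, covariates = c("sex", "age", "center")) {
  df <- as.data.frame(panel)
  df$g_add <- as.numeric(df$g_add)
  df$t2d <- as.logical(df$t2d_prevalent)
  df$visit <- factor(df$visit_year)
  both_strata <- length(unique(df$t2d)) > 1
  for (tl in unique(df$t2d))
    if (length(unique(df$g_add[df$t2d == tl])) < 2)
      stop("fewer than 2 genotype groups within a T2D stratum")
  covariates <- intersect(covariates, names(df))
  cov_part <- if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""
  geno_part <- if (both_strata) "g_add * t2d" else "g_add"
  fml <- stats::as.formula(paste(
    "bmi ~", geno_part, "+ visit", cov_part, "+ (1 | subject_id)"))
  fit <- lmerTest::lmer(fml, data = df, REML = TRUE)
  an <- stats::anova(fit, type = 3)
  p_geno <- an["g_add", "Pr(>F)"]
  p_int <- if (both_strata) an["g_add:t2d", "Pr(>F)"] else NA_real_

  grid <- expand.grid(g_add = sort(unique(df$g_add)),
                      t2d = unique(df$t2d),
                      visit = levels(df$visit))
  means <- apply(grid, 1, function(row) {
    nd <- df
    nd$g_add <- as.numeric(row[["g_add"]])
    nd$t2d <- as.logical(row[["t2d"]])
    nd$visit <- factor(row[["visit"]], levels = levels(df$visit))
    mean(stats::predict(fit, newdata = nd, re.form = NA))
  })
  adjusted <- data.frame(t2d = as.logical(grid$t2d),
                         genotype = as.numeric(grid$g_add),
                         visit_year = as.integer(as.character(grid$visit)),
                         mean = as.numeric(means))
  list(p_genotype = p_geno, p_interaction = p_int,
       adjusted_means = adjusted, model = fit)
}
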