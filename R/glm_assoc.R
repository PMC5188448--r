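# Logistic and linear association engine: stratified odds ratios,
# gene x environment interaction tests, and covariate-adjusted genotype
# means for continuous obesity-related traits.
#
# Two covariate sets are used throughout, mirroring common epidemiological
# practice: a basic model (sex, age, recruitment centre, and for
# time-to-event analyses the intervention arm) and a fully adjusted model
# adding total energy intake, Mediterranean-diet adherence, alcohol,
# smoking, physical activity, dyslipidemia and hypertension.

covariate_set <- function(model = c("model1", "model2"), include_arm = FALSE) {
  model <- match.arg(model)
  base <- c("sex", "age", "center", if (include_arm) "arm")
  if (model == "model1") base else c(base, .COVARIATE_COLS)
}

#' Fit a logistic regression model
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least
#' squares, convergence when the relative deviance change drops below
#' 1e-10, at most 100 iterations) with guards against rank deficiency
#' and perfect separation.
#'
#' @param outcome logical/0-1 outcome vector.
#' @param design data.frame of predictors (numeric, logical or factor).
#' @return the fitted `glm` object.
#' @export
fit_logistic <- function(outcome, design) {
  outcome <- as.logical(outcome)
  df <- data.frame(.y = outcome, design, check.names = TRUE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$.y)) < 2)
    stop("outcome has a single class; logistic model is undefined")
  mm <- stats::model.matrix(.y ~ ., data = df)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    alias <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(alias, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm(
    .y ~ ., family = stats::binomial(), data = df,
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  eta <- abs(stats::predict(fit, type = "link"))
  if (!fit$converged || (max(eta) > 15 && max(abs(stats::coef(fit)), na.rm = TRUE) > 10))
    stop("perfect separation (or non-convergence) detected; no estimates returned")
  fit
}

# Model-frame assembly shared by the logistic/linear routines: outcome,
# genotype contrast columns, covariates; complete-case within analysis.
build_assoc_frame <- function(cohort, snp, outcome, model, coding,
                              include_arm = FALSE, extra = character()) {
  ann <- snp_annotation_row(attr(cohort, "annotation"), snp)
  calls <- cohort_calls(cohort, snp)
  covs <- covariate_set(model, include_arm)
  df <- as.data.frame(cohort)[, unique(c(outcome, covs, extra)), drop = FALSE]
  if (coding == "codominant") {
    cm <- code_genotype(calls, ann, "codominant")
    df$g_het <- cm[, "het"]
    df$g_hom <- cm[, "hom"]
    geno_terms <- c("g_het", "g_hom")
  } else {
    df$g_code <- code_genotype(calls, ann, coding)
    geno_terms <- "g_code"
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  other <- setdiff(c(ann$allele_a, ann$allele_b), ann$risk_allele)
  labels <- switch(coding,
    codominant = c(paste0(other, ann$risk_allele, " vs ", other, other),
                   paste0(ann$risk_allele, ann$risk_allele, " vs ", other, other)),
    additive = "per risk allele",
    recessive = paste0(ann$risk_allele, ann$risk_allele, " vs ", other, "-carriers"))
  list(data = df, geno_terms = geno_terms, labels = labels,
       covariates = covs, ann = ann)
}

glm_fit_terms <- function(df, outcome, terms) {
  keep <- drop_constant_columns(df[, c(outcome, terms), drop = FALSE],
                                protect = outcome)
  fit_logistic(keep$data[[outcome]],
               keep$data[, setdiff(names(keep$data), outcome), drop = FALSE])
}

extract_or_rows <- function(fit, geno_terms, labels, stratum, model, n) {
  sm <- summary(fit)$coefficients
  out <- lapply(seq_along(geno_terms), function(i) {
    term <- geno_terms[i]
    if (!term %in% rownames(sm)) {
      return(data.frame(stratum = stratum, model = model, contrast = labels[i],
                        n = n, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_))
    }
    b <- sm[term, "Estimate"]; se <- sm[term, "Std. Error"]
    ci <- wald_exp_ci(b, se)
    data.frame(stratum = stratum, model = model, contrast = labels[i], n = n,
               or = exp(b), ci_low = ci[1], ci_high = ci[2],
               p_value = sm[term, "Pr(>|z|)"])
  })
  do.call(rbind, out)
}

#' Stratified odds ratios for a SNP
#'
#' Within each level of the stratifying variable, fits a multivariable
#' logistic model of the outcome on the genotype contrasts (codominant
#' by default, homozygous non-risk reference) plus the chosen covariate
#' set, and reports per-contrast odds ratios with Wald 95% CIs, the
#' global polymorphism p (likelihood-ratio test of all genotype
#' contrasts jointly) and the genotype x stratum interaction p.
#'
#' @param cohort a `grs_cohort`.
#' @param snp SNP id present in the cohort.
#' @param outcome `"t2d_prevalent"` or `"obesity"`.
#' @param stratify_by `"obesity"` or `"t2d_prevalent"` (must differ from
#'   the outcome).
#' @param model `"model1"` (sex, age, centre) or `"model2"` (plus the
#'   seven lifestyle/clinical covariates).
#' @param coding genetic model for the genotype term.
#' @return data.frame with one row per contrast x stratum; attributes
#'   `global_p` (named per stratum) and `p_interaction`.
#' @export
stratified_or <- function(cohort, snp, outcome = "t2d_prevalent",
                          stratify_by = if (outcome == "obesity") "t2d_prevalent" else "obesity",
                          model = c("model1", "model2"),
                          coding = c("codominant", "additive", "recessive")) {
  model <- match.arg(model); coding <- match.arg(coding)
  if (identical(outcome, stratify_by))
    stop("stratifying variable must differ from the outcome")
  fr <- build_assoc_frame(cohort, snp, outcome, model, coding,
                          extra = stratify_by)
  df <- fr$data
  strata <- stratum_levels(stratify_by)
  rows <- list(); global_p <- c()
  for (lev in names(strata)) {
    sub <- df[df[[stratify_by]] == strata[[lev]],
              setdiff(names(df), stratify_by), drop = FALSE]
    n <- nrow(sub)
    res <- tryCatch({
      full <- glm_fit_terms(sub, outcome, c(fr$geno_terms, fr$covariates))
      red <- glm_fit_terms(sub, outcome, fr$covariates)
      gp <- lrt_pvalue(red, full, df = length(fr$geno_terms))$p_value
      list(rows = extract_or_rows(full, fr$geno_terms, fr$labels, lev, model, n),
           gp = gp)
    }, error = function(e) {
      warning("stratum '", lev, "': ", conditionMessage(e), call. = FALSE)
      list(rows = data.frame(stratum = lev, model = model,
                             contrast = fr$labels, n = n, or = NA_real_,
                             ci_low = NA_real_, ci_high = NA_real_,
                             p_value = NA_real_),
           gp = NA_real_)
    })
    rows[[lev]] <- res$rows
    global_p[lev] <- res$gp
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  p_int <- tryCatch(
    interaction_test(cohort, snp, modifier = stratify_by, outcome = outcome,
                     model = model, coding = coding)$p_value,
    error = function(e) {
      warning("interaction test undefined: ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
  structure(out, global_p = global_p, p_interaction = p_int)
}

stratum_levels <- function(stratify_by) {
  if (stratify_by == "obesity")
    list("non-obese" = FALSE, "obese" = TRUE)
  else
    list("non-T2D" = FALSE, "T2D" = TRUE)
}

#' Genotype x modifier interaction test
#'
#' Likelihood-ratio test comparing the logistic model with genotype,
#' modifier and covariates against the same model plus the genotype x
#' modifier product term(s); degrees of freedom equal the number of
#' genotype contrasts (2 codominant, 1 additive/recessive).
#'
#' @inheritParams stratified_or
#' @param modifier name of the boolean effect modifier column.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
interaction_test <- function(cohort, snp, modifier = "obesity",
                             outcome = "t2d_prevalent",
                             model = c("model1", "model2"),
                             coding = c("codominant", "additive", "recessive")) {
  model <- match.arg(model); coding <- match.arg(coding)
  fr <- build_assoc_frame(cohort, snp, outcome, model, coding, extra = modifier)
  df <- fr$data
  for (g in fr$geno_terms) df[[paste0(g, "_x")]] <- df[[g]] * df[[modifier]]
  red <- glm_fit_terms(df, outcome, c(fr$geno_terms, modifier, fr$covariates))
  full <- glm_fit_terms(df, outcome, c(fr$geno_terms, modifier, fr$covariates,
                                       paste0(fr$geno_terms, "_x")))
  lrt_pvalue(red, full, df = length(fr$geno_terms))
}

#' Adjusted genotype means for a continuous trait
#'
#' Within each stratum (T2D status by default), fits a linear model of
#' the trait on the codominant genotype contrasts plus covariates and
#' reports covariate-adjusted genotype means (marginal standardisation:
#' predictions averaged over the observed covariate distribution).  The
#' genotype x stratum interaction is tested by an F-test on the product
#' terms in the pooled model.
#'
#' @inheritParams stratified_or
#' @param trait name of the numeric trait column (e.g. `"bmi"`).
#' @return list with `adjusted_means` (data.frame: stratum, genotype,
#'   mean, se, n), `p_interaction` and per-stratum genotype `global_p`.
#' @export
fit_linear_trait <- function(cohort, snp, trait = "bmi",
                             stratify_by = "t2d_prevalent",
                             model = c("model1", "model2")) {
  model <- match.arg(model)
  fr <- build_assoc_frame(cohort, snp, trait, model, "codominant",
                          extra = stratify_by)
  df <- fr$data
  ann <- fr$ann
  other <- setdiff(c(ann$allele_a, ann$allele_b), ann$risk_allele)
  geno_labels <- c(paste0(other, other), paste0(other, ann$risk_allele),
                   paste0(ann$risk_allele, ann$risk_allele))

  # pooled interaction F-test (constant covariates, e.g. a single centre,
  # drop out of the design)
  fr$covariates <- fr$covariates[vapply(fr$covariates, function(cv)
    length(unique(df[[cv]])) > 1, logical(1))]
  fml_cov <- paste(c(fr$covariates, stratify_by), collapse = " + ")
  red <- stats::lm(stats::as.formula(paste(
    trait, "~ g_het + g_hom +", fml_cov)), data = df)
  full <- stats::lm(stats::as.formula(paste(
    trait, "~ (g_het + g_hom) *", stratify_by, "+", fml_cov)), data = df)
  p_int <- stats::anova(red, full)[2, "Pr(>F)"]

  strata <- stratum_levels(stratify_by)
  means <- list(); global_p <- c()
  for (lev in names(strata)) {
    sub <- df[df[[stratify_by]] == strata[[lev]], , drop = FALSE]
    keep <- drop_constant_columns(
      sub[, c(trait, "g_het", "g_hom", fr$covariates), drop = FALSE],
      protect = c(trait, "g_het", "g_hom"))
    fit <- stats::lm(stats::as.formula(paste(trait, "~ .")), data = keep$data)
    fit0 <- stats::lm(stats::as.formula(paste(trait, "~ .")),
                      data = keep$data[, setdiff(names(keep$data),
                                                 c("g_het", "g_hom")),
                                       drop = FALSE])
    global_p[lev] <- stats::anova(fit0, fit)[2, "Pr(>F)"]
    mm <- stats::model.matrix(fit)
    for (k in 0:2) {
      mg <- mm
      mg[, "g_het"] <- as.numeric(k == 1)
      mg[, "g_hom"] <- as.numeric(k == 2)
      xbar <- colMeans(mg)
      est <- sum(xbar * stats::coef(fit))
      se <- sqrt(drop(t(xbar) %*% stats::vcov(fit) %*% xbar))
      means[[length(means) + 1L]] <- data.frame(
        stratum = lev, genotype = geno_labels[k + 1], mean = est, se = se,
        n = sum((k == 0 & sub$g_het == 0 & sub$g_hom == 0) |
                  (k == 1 & sub$g_het == 1) | (k == 2 & sub$g_hom == 1)))
    }
  }
  list(adjusted_means = do.call(rbind, means), p_interaction = p_int,
       global_p = global_p)
}
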