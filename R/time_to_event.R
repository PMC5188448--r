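# Incidence analysis in baseline-T2D-free subjects: person-years, crude
# incidence rates, Cox proportional-hazards models with gene x obesity
# interaction, and Kaplan-Meier one-minus-survival curves.

incidence_subset <- function(cohort) {
  df <- as.data.frame(cohort)
  df <- df[!df$t2d_prevalent & !is.na(df$followup_years), , drop = FALSE]
  if (any(df$followup_years < 0)) stop("negative follow-up time encountered")
  if (any(df$followup_years == 0)) {
    df <- df[df$followup_years > 0, , drop = FALSE]
  }
  df
}

#' Person-years of follow-up
#'
#' Sum of individual follow-up durations, optionally by group.
#'
#' @param followup_years non-negative numeric durations.
#' @param by optional grouping factor.
#' @return total person-years (scalar) or a named vector per group.
#' @export
person_time <- function(followup_years, by = NULL) {
  if (any(is.na(followup_years))) stop("missing follow-up time")
  if (any(followup_years < 0)) stop("negative follow-up time encountered")
  if (is.null(by)) return(sum(followup_years))
  tapply(followup_years, by, sum)
}

#' Crude incidence rate per 1000 person-years
#'
#' @param n_cases integer number of incident cases.
#' @param person_years positive person-years at risk.
#' @return rate per 1000 person-years (unrounded; study tables report it
#'   to one decimal).
#' @export
incidence_rate <- function(n_cases, person_years) {
  stopifnot(n_cases >= 0)
  if (any(person_years <= 0)) stop("person-years must be positive")
  1000 * n_cases / person_years
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood maximisation with Efron handling of tied event
#' times; Wald confidence intervals.
#'
#' @param durations non-negative follow-up times.
#' @param events logical/0-1 event indicator.
#' @param design data.frame of predictors.
#' @return the fitted `coxph` object.
#' @export
fit_cox <- function(durations, events, design) {
  events <- as.numeric(events)
  if (sum(events, na.rm = TRUE) == 0) stop("no events; Cox model is undefined")
  df <- data.frame(.t = durations, .e = events, design, check.names = TRUE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- survival::coxph(survival::Surv(.t, .e) ~ ., data = df,
                         ties = "efron")
  if (any(is.na(stats::coef(fit))))
    stop("design is rank deficient; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  mono <- sqrt(diag(fit$var)) > 100
  if (any(mono))
    warning("monotone likelihood suspected for: ",
            paste(names(stats::coef(fit))[mono], collapse = ", "))
  fit
}

cox_fit_terms <- function(df, terms) {
  keep <- drop_constant_columns(df[, c(".t", ".e", terms), drop = FALSE],
                                protect = c(".t", ".e"))
  fit_cox(keep$data$.t, keep$data$.e,
          keep$data[, setdiff(names(keep$data), c(".t", ".e")), drop = FALSE])
}

extract_hr_rows <- function(fit, geno_terms, labels) {
  sm <- summary(fit)$coefficients
  out <- lapply(seq_along(geno_terms), function(i) {
    term <- geno_terms[i]
    if (!term %in% rownames(sm))
      return(data.frame(contrast = labels[i], hr = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_))
    b <- sm[term, "coef"]; se <- sm[term, "se(coef)"]
    ci <- wald_exp_ci(b, se)
    data.frame(contrast = labels[i], hr = exp(b), ci_low = ci[1],
               ci_high = ci[2], p_value = sm[term, "Pr(>|z|)"])
  })
  do.call(rbind, out)
}

#' Obesity-stratified Cox analysis with interaction test
#'
#' In the baseline-T2D-free subset, computes per genotype x obesity cell
#' the incident case count, person-years and crude incidence rate, fits
#' within-stratum Cox models (genotype contrasts vs homozygous non-risk
#' reference plus covariates) and tests the genotype x obesity
#' interaction by a likelihood-ratio test on the product terms.
#' Recessive-model hazard ratios (homozygous risk vs common-allele
#' carriers) are reported alongside the codominant contrasts.
#'
#' @inheritParams stratified_or
#' @param stratify_by stratifying boolean column, default `"obesity"`.
#' @return list with `cells` (counts, person-years, rates per genotype x
#'   stratum), `hr` (codominant per-stratum hazard ratios with global p),
#'   `hr_recessive`, `p_interaction` (codominant LRT) and
#'   `p_interaction_recessive`.
#' @export
cox_stratified_and_interaction <- function(cohort, snp,
                                           stratify_by = "obesity",
                                           model = c("model1", "model2")) {
  model <- match.arg(model)
  df <- incidence_subset(cohort)
  ann <- snp_annotation_row(attr(cohort, "annotation"), snp)
  calls <- df[[geno_col(snp)]]
  cm <- code_genotype(calls, ann, "codominant")
  add <- code_genotype(calls, ann, "additive")
  other <- setdiff(c(ann$allele_a, ann$allele_b), ann$risk_allele)
  geno_label <- c(paste0(other, other), paste0(other, ann$risk_allele),
                  paste0(ann$risk_allele, ann$risk_allele))[add + 1]

  covs <- covariate_set(model, include_arm = TRUE)
  base <- data.frame(.t = df$followup_years, .e = as.numeric(df$t2d_incident),
                     g_het = cm[, "het"], g_hom = cm[, "hom"],
                     g_rec = as.numeric(add == 2),
                     stratum = df[[stratify_by]],
                     df[, covs, drop = FALSE], check.names = FALSE)
  base$geno <- geno_label
  base <- base[stats::complete.cases(base), , drop = FALSE]

  # per-cell counts, person-years, crude rates
  strata <- stratum_levels(stratify_by)
  cells <- do.call(rbind, lapply(names(strata), function(lev) {
    sub <- base[base$stratum == strata[[lev]], ]
    do.call(rbind, lapply(sort(unique(geno_label)), function(g) {
      gs <- sub[sub$geno == g, ]
      py <- sum(gs$.t)
      data.frame(stratum = lev, genotype = g, n_cases = sum(gs$.e),
                 n_noncases = sum(gs$.e == 0), person_years = py,
                 incidence_rate = if (py > 0) incidence_rate(sum(gs$.e), py) else NA_real_)
    }))
  }))

  labels <- c(paste0(other, ann$risk_allele, " vs ", other, other),
              paste0(ann$risk_allele, ann$risk_allele, " vs ", other, other))
  rec_label <- paste0(ann$risk_allele, ann$risk_allele, " vs ", other, "-carriers")

  hr <- list(); hr_rec <- list(); global_p <- c()
  for (lev in names(strata)) {
    sub <- base[base$stratum == strata[[lev]], , drop = FALSE]
    res <- tryCatch({
      full <- cox_fit_terms(sub, c("g_het", "g_hom", covs))
      red <- cox_fit_terms(sub, covs)
      gp <- lrt_pvalue(red, full, df = 2)$p_value
      rows <- extract_hr_rows(full, c("g_het", "g_hom"), labels)
      rec <- extract_hr_rows(cox_fit_terms(sub, c("g_rec", covs)), "g_rec",
                             rec_label)
      list(rows = rows, rec = rec, gp = gp)
    }, error = function(e) {
      warning("stratum '", lev, "': ", conditionMessage(e), call. = FALSE)
      list(rows = data.frame(contrast = labels, hr = NA_real_,
                             ci_low = NA_real_, ci_high = NA_real_,
                             p_value = NA_real_),
           rec = data.frame(contrast = rec_label, hr = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p_value = NA_real_),
           gp = NA_real_)
    })
    res$rows$stratum <- lev; res$rec$stratum <- lev
    hr[[lev]] <- res$rows; hr_rec[[lev]] <- res$rec
    global_p[lev] <- res$gp
  }

  p_int <- cox_interaction_p(base, c("g_het", "g_hom"), covs)
  p_int_rec <- cox_interaction_p(base, "g_rec", covs)

  list(cells = cells,
       hr = {h <- do.call(rbind, hr); rownames(h) <- NULL; h},
       hr_recessive = {h <- do.call(rbind, hr_rec); rownames(h) <- NULL; h},
       global_p = global_p, model = model,
       p_interaction = p_int, p_interaction_recessive = p_int_rec)
}

cox_interaction_p <- function(base, geno_terms, covs) {
  df <- base
  df$stratum <- as.numeric(df$stratum)
  for (g in geno_terms) df[[paste0(g, "_x")]] <- df[[g]] * df$stratum
  tryCatch({
    red <- cox_fit_terms(df, c(geno_terms, "stratum", covs))
    full <- cox_fit_terms(df, c(geno_terms, "stratum", covs,
                                paste0(geno_terms, "_x")))
    lrt_pvalue(red, full, df = length(geno_terms))$p_value
  }, error = function(e) NA_real_)
}

#' Kaplan-Meier one-minus-survival curves
#'
#' Product-limit estimate of the cumulative event probability
#' (1 - S(t)) per group, as used to display time to type-2 diabetes by
#' genotype.
#'
#' @param durations non-negative follow-up times.
#' @param events logical/0-1 event indicator.
#' @param groups optional grouping vector; a single curve if omitted.
#' @return data.frame with columns `group`, `time`, `cuminc`
#'   (1 - survival, right-continuous step values at event times),
#'   `n_risk`, `n_event`.
#' @export
km_one_minus_survival <- function(durations, events, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(durations))
  df <- data.frame(.t = durations, .e = as.numeric(events), .g = groups)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  out <- lapply(split(df, df$.g), function(sub) {
    if (nrow(sub) == 0) return(NULL)
    sf <- survival::survfit(survival::Surv(.t, .e) ~ 1, data = sub)
    data.frame(group = sub$.g[1], time = sf$time, cuminc = 1 - sf$surv,
               n_risk = sf$n.risk, n_event = sf$n.event)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
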