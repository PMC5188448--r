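# Obesity-specific genetic risk scores (GRS).
#
# The central procedure: each candidate T2D SNP is screened for
# association with prevalent T2D separately in obese and non-obese
# subjects; SNPs are then partitioned into two unweighted additive
# scores, one holding the SNPs more strongly associated in non-obese
# subjects (nobGRS) and one holding those more strongly associated in
# obese subjects (obGRS).  Each score is the plain count of risk
# alleles (0-2 per SNP), and its predictive value is evaluated per
# stratum by the area under the ROC curve.

#' Screen SNPs for T2D association by obesity stratum
#'
#' For each SNP, fits an additive-coded logistic model of prevalent T2D
#' adjusted for age, sex and (where not fixed by the stratum) obesity,
#' in the total sample and within the obese and non-obese strata.
#'
#' @param cohort a `grs_cohort`.
#' @param snps character vector of SNP ids (default: all annotated SNPs
#'   with genotype columns present).
#' @return data.frame of class `grs_screen`: one row per SNP x stratum
#'   (`total`, `non-obese`, `obese`) with per-allele `or`, `ci_low`,
#'   `ci_high`, `p_value`, `n` and a `note` for SNPs whose fit failed
#'   (e.g. monomorphic).
#' @export
screen_snps <- function(cohort, snps = NULL) {
  ann_all <- attr(cohort, "annotation")
  if (is.null(snps))
    snps <- ann_all$snp_id[geno_col(ann_all$snp_id) %in% names(cohort)]
  if (!length(snps)) stop("no SNPs with genotype data to screen")
  df <- as.data.frame(cohort)
  strata <- list(total = rep(TRUE, nrow(df)),
                 "non-obese" = !df$obesity, obese = df$obesity)
  rows <- list()
  for (snp in snps) {
    ann <- snp_annotation_row(ann_all, snp)
    code <- code_genotype(df[[geno_col(snp)]], ann, "additive")
    for (lev in names(strata)) {
      sub <- df[strata[[lev]], , drop = FALSE]
      g <- code[strata[[lev]]]
      keep <- stats::complete.cases(sub[, c("t2d_prevalent", "age", "sex")]) & !is.na(g)
      sub <- sub[keep, , drop = FALSE]; g <- g[keep]
      row <- data.frame(snp_id = snp, gene_label = ann$gene_label,
                        stratum = lev, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        n = nrow(sub), note = "")
      res <- tryCatch({
        design <- data.frame(g_code = g, age = sub$age, sex = sub$sex)
        if (lev == "total") design$obesity <- sub$obesity
        if (length(unique(g)) < 2) stop("monomorphic in stratum")
        fit <- fit_logistic(sub$t2d_prevalent, design)
        sm <- summary(fit)$coefficients
        ci <- wald_exp_ci(sm["g_code", "Estimate"], sm["g_code", "Std. Error"])
        row$or <- exp(sm["g_code", "Estimate"])
        row$ci_low <- ci[1]; row$ci_high <- ci[2]
        row$p_value <- sm["g_code", "Pr(>|z|)"]
        row
      }, error = function(e) {
        row$note <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("grs_screen", "data.frame")
  out
}

#' Partition screened SNPs into obesity-specific GRS sets
#'
#' A SNP joins the stratum-specific score for the stratum in which its
#' screening p-value is smaller, provided that smaller p-value is below
#' `alpha_in`; SNPs reaching the threshold in neither stratum are
#' excluded.  The rule and threshold are recorded in the result so the
#' partition is auditable.
#'
#' @param table a `grs_screen` data.frame.
#' @param alpha_in entry p-value threshold (default 0.10, capturing
#'   "significant or near-significant" stratum associations).
#' @return list of class `grs_partition` with `nob_set`, `ob_set`,
#'   `excluded` (data.frame with reasons), `alpha_in` and `rule`.
#' @export
partition_snps <- function(table, alpha_in = 0.10) {
  stopifnot(inherits(table, "data.frame"))
  snps <- unique(table$snp_id)
  nob <- character(); ob <- character()
  excluded <- data.frame(snp_id = character(), reason = character())
  for (snp in snps) {
    p_nob <- table$p_value[table$snp_id == snp & table$stratum == "non-obese"]
    p_ob <- table$p_value[table$snp_id == snp & table$stratum == "obese"]
    if (!length(p_nob) || !length(p_ob))
      stop("screen table is incomplete for ", snp,
           ": both obesity strata are required")
    if (is.na(p_nob) || is.na(p_ob)) {
      excluded <- rbind(excluded, data.frame(snp_id = snp,
                                             reason = "undefined stratum fit"))
    } else if (min(p_nob, p_ob) >= alpha_in) {
      excluded <- rbind(excluded, data.frame(
        snp_id = snp, reason = sprintf("min stratum p %.3f >= alpha_in %.2f",
                                       min(p_nob, p_ob), alpha_in)))
    } else if (p_nob <= p_ob) {
      nob <- c(nob, snp)
    } else {
      ob <- c(ob, snp)
    }
  }
  structure(list(nob_set = nob, ob_set = ob, excluded = excluded,
                 alpha_in = alpha_in,
                 rule = "assign to stratum with smaller screening p; require min p < alpha_in"),
            class = "grs_partition")
}

#' @exportS3Method base::print
print.grs_partition <- function(x, ...) {
  cat("<grs_partition> rule:", x$rule, "(alpha_in =", x$alpha_in, ")\n")
  cat("  nobGRS:", paste(x$nob_set, collapse = ", "), "\n")
  cat("  obGRS: ", paste(x$ob_set, collapse = ", "), "\n")
  if (nrow(x$excluded)) cat("  excluded:", paste(x$excluded$snp_id, collapse = ", "), "\n")
  invisible(x)
}

#' Compute an unweighted genetic risk score
#'
#' Sum of risk-allele counts (0/1/2 per SNP) over a SNP set.  Subjects
#' missing any member genotype receive a missing score (no prorating).
#'
#' @param cohort a `grs_cohort`.
#' @param snp_set character vector of SNP ids.
#' @return integer vector of scores in `[0, 2 * length(snp_set)]`, `NA`
#'   where any member genotype is missing.
#' @export
compute_grs <- function(cohort, snp_set) {
  ann_all <- attr(cohort, "annotation")
  if (!length(snp_set)) stop("empty SNP set")
  codes <- sapply(snp_set, function(snp) {
    ann <- snp_annotation_row(ann_all, snp)
    if (is.na(ann$risk_allele)) stop("SNP ", snp, " has no risk-allele annotation")
    code_genotype(cohort_calls(cohort, snp), ann, "additive")
  })
  codes <- matrix(codes, ncol = length(snp_set))
  score <- rowSums(codes)
  as.integer(score)
}

#' GRS-T2D association
#'
#' Per-point (per risk allele) odds ratio for prevalent T2D from a
#' logistic model with the GRS entered as a continuous covariate,
#' adjusted for age, sex and (overall model only) obesity; fitted
#' overall and within each obesity stratum.
#'
#' @param cohort a `grs_cohort`.
#' @param score integer GRS per subject (as from [compute_grs()]).
#' @return data.frame: one row per stratum (`total`, `non-obese`,
#'   `obese`) with `or`, `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
grs_association <- function(cohort, score) {
  df <- as.data.frame(cohort)
  df$.score <- score
  strata <- list(total = rep(TRUE, nrow(df)),
                 "non-obese" = !df$obesity, obese = df$obesity)
  rows <- lapply(names(strata), function(lev) {
    sub <- df[strata[[lev]], , drop = FALSE]
    sub <- sub[stats::complete.cases(sub[, c(".score", "t2d_prevalent",
                                             "age", "sex")]), , drop = FALSE]
    if (length(unique(sub$.score)) < 2)
      stop("GRS is constant within stratum '", lev, "'")
    design <- data.frame(score = sub$.score, age = sub$age, sex = sub$sex)
    if (lev == "total" && length(unique(sub$obesity)) > 1)
      design$obesity <- sub$obesity
    fit <- fit_logistic(sub$t2d_prevalent, design)
    sm <- summary(fit)$coefficients
    ci <- wald_exp_ci(sm["score", "Estimate"], sm["score", "Std. Error"])
    data.frame(stratum = lev, or = exp(sm["score", "Estimate"]),
               ci_low = ci[1], ci_high = ci[2],
               p_value = sm["score", "Pr(>|z|)"], n = nrow(sub))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROC curve and AUC for a score
#'
#' Area under the ROC curve by the rank (Mann-Whitney) construction
#' with ties counted one half; two-sided p-value against AUC = 0.5 from
#' the tie-corrected normal approximation to the Mann-Whitney statistic.
#' An optional seeded bootstrap supplies a percentile confidence
#' interval.
#'
#' @param score numeric predictor (higher = more disease-like).
#' @param outcome logical/0-1 disease indicator.
#' @param n_boot bootstrap resamples for the percentile CI (0 = skip).
#' @param seed seed for the bootstrap.
#' @return list of class `roc_result`: `auc`, `p_value`, `n_cases`,
#'   `n_controls`, `curve` (data.frame `fpr`, `tpr`, monotone
#'   non-decreasing), and `ci_low`/`ci_high` when bootstrapped.
#' @export
roc_auc <- function(score, outcome, n_boot = 0, seed = NULL) {
  outcome <- as.logical(outcome)
  keep <- !is.na(score) & !is.na(outcome)
  score <- score[keep]; outcome <- outcome[keep]
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  auc <- auc_rank(score, outcome)

  # tie-corrected normal approximation to the Mann-Whitney null
  n <- n1 + n0
  ties <- table(score)
  sigma2 <- (n1 * n0 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  u <- auc * n1 * n0
  z <- (u - n1 * n0 / 2) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))

  # empirical ROC step curve over the distinct thresholds
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(score[outcome] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(score[!outcome] >= t), numeric(1))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))

  out <- list(auc = auc, p_value = p, n_cases = n1, n_controls = n0,
              curve = curve)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(length(score), replace = TRUE)
        if (length(unique(outcome[idx])) < 2) return(NA_real_)
        auc_rank(score[idx], outcome[idx])
      }, numeric(1))
    })
    qs <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    out$ci_low <- qs[1]; out$ci_high <- qs[2]
  }
  class(out) <- "roc_result"
  out
}

auc_rank <- function(score, outcome) {
  r <- rank(score)
  n1 <- sum(outcome); n0 <- sum(!outcome)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @exportS3Method base::print
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (cases %d, controls %d), p vs 0.5 = %.3g\n",
              x$auc, x$n_cases, x$n_controls, x$p_value))
  if (!is.null(x$ci_low))
    cat(sprintf("  bootstrap 95%% CI: %.3f-%.3f\n", x$ci_low, x$ci_high))
  invisible(x)
}
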