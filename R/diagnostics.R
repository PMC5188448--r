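# Classification-style predictive values for a genetic test (e.g. the
# recessive TT-carrier model for incident T2D), by obesity stratum.

#' Sensitivity, specificity and predictive values of a binary test
#'
#' Treats a binary genetic classification (e.g. homozygous risk-allele
#' carrier) as a screening test for a binary outcome and reports
#' sensitivity, specificity, PPV and NPV with exact (Clopper-Pearson)
#' 95% confidence intervals, plus the Pearson chi-square association p
#' for the 2x2 table (Fisher's exact test is substituted, and noted,
#' when any expected cell count is below 5).
#'
#' @param test logical test-positive indicator.
#' @param outcome logical disease indicator.
#' @param stratum optional label carried through to the result.
#' @return list of class `diagnostic_result`: counts `tp`, `fp`, `fn`,
#'   `tn`; `sensitivity`, `specificity`, `ppv`, `npv` each a vector
#'   `(estimate, ci_low, ci_high)` (`NA` where the denominator is
#'   empty); `p_value`; `test_used`; `stratum`.
#' @export
predictive_values <- function(test, outcome, stratum = "all") {
  keep <- !is.na(test) & !is.na(outcome)
  test <- as.logical(test)[keep]; outcome <- as.logical(outcome)[keep]
  if (!length(test)) stop("empty stratum")
  tp <- sum(test & outcome); fp <- sum(test & !outcome)
  fn <- sum(!test & outcome); tn <- sum(!test & !outcome)

  prop_ci <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    ci <- stats::binom.test(x, n)$conf.int
    c(x / n, ci[1], ci[2])
  }
  tab <- matrix(c(tp, fp, fn, tn), nrow = 2, byrow = TRUE)
  p <- NA_real_; test_used <- NA_character_
  if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      p <- stats::fisher.test(tab)$p.value
      test_used <- "fisher"
      message("expected cell count < 5; Fisher's exact test used")
    } else {
      p <- stats::chisq.test(tab, correct = FALSE)$p.value
      test_used <- "pearson"
    }
  }
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = prop_ci(tp, tp + fn),
    specificity = prop_ci(tn, tn + fp),
    ppv = prop_ci(tp, tp + fp),
    npv = prop_ci(tn, tn + fn),
    p_value = p, test_used = test_used, stratum = stratum
  ), class = "diagnostic_result")
}

#' @exportS3Method base::print
print.diagnostic_result <- function(x, ...) {
  cat("stratum:", x$stratum, " (TP", x$tp, "FP", x$fp, "FN", x$fn,
      "TN", x$tn, ")\n")
  for (m in c("sensitivity", "specificity", "ppv", "npv"))
    cat(sprintf("  %-12s %.3f (95%% CI %.3f-%.3f)\n", m, x[[m]][1],
                x[[m]][2], x[[m]][3]))
  cat(sprintf("  association p = %.3g (%s)\n", x$p_value, x$test_used))
  invisible(x)
}

# One-row summary used by the pipeline's TSV export.
diagnostic_row <- function(x) {
  data.frame(stratum = x$stratum, tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
             sensitivity = x$sensitivity[1], specificity = x$specificity[1],
             ppv = x$ppv[1], npv = x$npv[1],
             sens_lo = x$sensitivity[2], sens_hi = x$sensitivity[3],
             spec_lo = x$specificity[2], spec_hi = x$specificity[3],
             p_value = x$p_value, test = x$test_used)
}
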