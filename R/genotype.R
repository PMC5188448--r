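#' Genotype counts for a biallelic SNP
#'
#' Tallies the three genotype classes of a vector of genotype calls
#' (two-character strings such as `"CT"`) relative to a SNP annotation.
#' Missing calls are excluded from the counts.
#'
#' @param calls character vector of genotype calls (`NA` for missing).
#' @param ann single-row SNP annotation (see [read_snp_annotation()]),
#'   providing `allele_a`, `allele_b` and `risk_allele`.
#' @return object of class `genotype_counts`: a list with `n_homref`
#'   (homozygous non-risk), `n_het` and `n_homalt` (homozygous risk),
#'   plus the allele labels used.
#' @export
genotype_counts <- function(calls, ann) {
  codes <- code_genotype(calls, ann, coding = "additive")
  structure(list(
    n_homref = sum(codes == 0, na.rm = TRUE),
    n_het    = sum(codes == 1, na.rm = TRUE),
    n_homalt = sum(codes == 2, na.rm = TRUE),
    risk_allele = ann$risk_allele,
    other_allele = setdiff(c(ann$allele_a, ann$allele_b), ann$risk_allele)
  ), class = "genotype_counts")
}

#' Construct genotype counts directly
#'
#' Convenience constructor when only the three class counts are known,
#' e.g. when re-analysing a published genotype table.
#'
#' @param n_homref,n_het,n_homalt non-negative integer counts of
#'   homozygous non-risk, heterozygous and homozygous risk genotypes.
#' @return a `genotype_counts` object.
#' @export
as_genotype_counts <- function(n_homref, n_het, n_homalt) {
  stopifnot(n_homref >= 0, n_het >= 0, n_homalt >= 0)
  structure(list(n_homref = n_homref, n_het = n_het, n_homalt = n_homalt,
                 risk_allele = NA_character_, other_allele = NA_character_),
            class = "genotype_counts")
}

#' Numeric coding of genotype calls
#'
#' Codes genotype calls relative to the declared risk allele under the
#' standard single-SNP genetic models: additive (0/1/2 risk-allele
#' count), recessive (1 for homozygous risk carriers, 0 otherwise) or
#' codominant (two indicator contrasts, heterozygote and homozygote
#' risk, against the homozygous non-risk reference).
#'
#' @param calls character vector of calls such as `"CC"`, `"CT"`;
#'   allele order within a call is irrelevant. `NA` propagates.
#' @param ann single-row SNP annotation with `allele_a`, `allele_b`,
#'   `risk_allele`.
#' @param coding one of `"additive"`, `"recessive"`, `"codominant"`.
#' @return numeric vector (additive, recessive) or a two-column matrix
#'   of indicators (codominant, columns `het` and `hom`).
#' @export
code_genotype <- function(calls, ann, coding = c("additive", "recessive", "codominant")) {
  coding <- match.arg(coding)
  risk <- ann$risk_allele
  alleles <- c(ann$allele_a, ann$allele_b)
  if (!risk %in% alleles)
    stop("risk allele '", risk, "' is not one of the declared alleles (",
         paste(alleles, collapse = "/"), ") for ", ann$snp_id)
  calls <- toupper(as.character(calls))
  calls[calls %in% c("", "NA", "--", "..")] <- NA_character_
  ok <- is.na(calls) | grepl(paste0("^[", paste(alleles, collapse = ""), "]{2}$"), calls)
  if (any(!ok))
    stop("invalid genotype call(s) for ", ann$snp_id, ": ",
         paste(unique(calls[!ok]), collapse = ", "))
  add <- ifelse(is.na(calls), NA_real_,
                vapply(strsplit(calls, ""), function(a) sum(a == risk), numeric(1)))
  switch(coding,
    additive = add,
    recessive = as.numeric(add == 2),
    codominant = cbind(het = as.numeric(add == 1), hom = as.numeric(add == 2))
  )
}

#' Genotype and allele frequencies
#'
#' Percentage of each genotype class and the risk-allele frequency,
#' computed from genotype counts.
#'
#' @param counts a `genotype_counts` object.
#' @return list with `pct` (named length-3 vector summing to 100 before
#'   rounding), `allele_freq` (risk-allele frequency) and `n_total`.
#' @export
genotype_frequencies <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  n <- counts$n_homref + counts$n_het + counts$n_homalt
  if (n <= 0) stop("no genotyped subjects: total count is zero")
  pct <- 100 * c(homref = counts$n_homref, het = counts$n_het,
                 homalt = counts$n_homalt) / n
  list(pct = pct,
       allele_freq = (counts$n_het + 2 * counts$n_homalt) / (2 * n),
       n_total = n)
}

#' Hardy-Weinberg equilibrium test
#'
#' Pearson chi-square goodness-of-fit test (1 df) of observed genotype
#' counts against the expected Hardy-Weinberg proportions computed from
#' the estimated allele frequency.  Used as a genotyping quality gate
#' before association analysis.
#'
#' @param counts a `genotype_counts` object.
#' @return list with `statistic`, `df` (1), `p_value`, `allele_freq`
#'   and `expected` counts.  A monomorphic SNP returns statistic 0 and
#'   p = 1.
#' @export
hwe_test <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  n <- counts$n_homref + counts$n_het + counts$n_homalt
  if (n <= 0) stop("no genotyped subjects: total count is zero")
  p <- (counts$n_het + 2 * counts$n_homalt) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(statistic = 0, df = 1L, p_value = 1, allele_freq = p,
                expected = c(homref = n * (1 - p)^2, het = 2 * n * p * (1 - p),
                             homalt = n * p^2)))
  }
  expected <- n * c(homref = (1 - p)^2, het = 2 * p * (1 - p), homalt = p^2)
  observed <- c(counts$n_homref, counts$n_het, counts$n_homalt)
  stat <- sum((observed - expected)^2 / expected)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       allele_freq = p, expected = expected)
}
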