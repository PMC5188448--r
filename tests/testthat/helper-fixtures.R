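# Fixtures built in code: tiny hand-written cohorts, genotype files and
# simulation shortcuts shared across the test files.

two_snp_annotation <- function() {
  ann <- data.frame(
    snp_id = c("rs7903146", "rs4402960"),
    gene_label = c("TCF7L2", "IGF2BP2"),
    allele_a = c("C", "G"), allele_b = c("T", "T"),
    risk_allele = c("T", "T"), stringsAsFactors = FALSE)
  class(ann) <- c("snp_annotation", "data.frame")
  ann
}

# Five-subject phenotype table with inline genotypes for the two SNPs.
tiny_pheno_df <- function() {
  data.frame(
    subject_id = paste0("P", 1:5),
    age = c(62, 70, 66, 59, 74),
    sex = c("male", "female", "female", "male", "female"),
    center = "C1",
    arm = c("control", "control", "MedDiet+EVOO", "MedDiet+nuts", "control"),
    bmi = c(27.5, 31.2, 29.9, 33.0, 25.1),
    t2d_prevalent = c(FALSE, TRUE, FALSE, FALSE, TRUE),
    followup_years = c(5.1, NA, 6.3, 2.2, NA),
    t2d_incident = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    "snp:rs7903146" = c("CC", "CT", "TT", "CT", "CC"),
    "snp:rs4402960" = c("GG", "GT", "TT", "GG", "GT"),
    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tiny_pheno <- function(df = tiny_pheno_df(),
                             path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Minimal VCF (v4.2, GT only) for the given call matrix.
write_tiny_vcf <- function(calls, annotation,
                           path = tempfile(fileext = ".vcf")) {
  samples <- rownames(calls)
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (j in seq_len(ncol(calls))) {
    snp <- colnames(calls)[j]
    ann <- annotation[annotation$snp_id == snp, ]
    ref <- ann$allele_a; alt <- ann$allele_b
    gts <- vapply(calls[, j], function(cl) {
      if (is.na(cl)) return("./.")
      a <- strsplit(cl, "")[[1]]
      paste(sort(as.integer(a == alt)), collapse = "/")
    }, character(1))
    lines <- c(lines, paste(c("1", 1000 + j, snp, ref, alt, ".", "PASS", ".",
                              "GT", gts), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# Cohort wrapper around a bare genotype/outcome design, with the
# mandatory phenotype columns held constant so that adjustment
# covariates drop out and toy fits reduce to the terms under study.
toy_cohort <- function(calls_rs7903146, t2d_prevalent,
                       obesity = rep(FALSE, length(t2d_prevalent)),
                       followup_years = rep(1, length(t2d_prevalent)),
                       t2d_incident = rep(FALSE, length(t2d_prevalent))) {
  n <- length(t2d_prevalent)
  df <- data.frame(
    subject_id = paste0("T", seq_len(n)),
    age = 65, sex = "male", center = "C1", arm = "control",
    bmi = ifelse(obesity, 32, 27),
    t2d_prevalent = t2d_prevalent,
    followup_years = followup_years,
    t2d_incident = t2d_incident,
    "snp:rs7903146" = calls_rs7903146,
    stringsAsFactors = FALSE, check.names = FALSE)
  suppressMessages(as_cohort(df, two_snp_annotation()))
}

# Genotype calls from additive codes for the TCF7L2 test SNP.
calls_from_codes <- function(codes) c("CC", "CT", "TT")[codes + 1]

expect_rel_equal <- function(x, y, tol = 1e-8) {
  expect_lt(abs(x - y) / max(abs(y), 1e-12), tol)
}
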