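# Genotype coding, frequencies, Hardy-Weinberg, and cohort loading.

test_that("a well-formed phenotype table round-trips through load_cohort", {
  path <- write_tiny_pheno()
  co <- load_cohort(path, annotation = two_snp_annotation())
  expect_s3_class(co, "grs_cohort")
  expect_equal(nrow(co), 5)
  expect_equal(co$obesity, co$bmi >= 30)
  expect_equal(co[["snp:rs7903146"]], tiny_pheno_df()[["snp:rs7903146"]])
  expect_equal(attr(co, "log")$n_dropped, 0)
})

test_that("rows failing validation are dropped and logged", {
  df <- tiny_pheno_df()
  df$bmi[2] <- NA
  path <- write_tiny_pheno(df)
  expect_message(co <- load_cohort(path, annotation = two_snp_annotation()),
                 "dropped 1 of 5")
  expect_equal(nrow(co), 4)
  expect_equal(attr(co, "log")$n_dropped, 1)
})

test_that("a missing mandatory column is a hard error naming the column", {
  df <- tiny_pheno_df()
  df$followup_years <- NULL
  path <- write_tiny_pheno(df)
  expect_error(load_cohort(path, annotation = two_snp_annotation()),
               "followup_years")
})

test_that("unknown subject ids in the genotype source are a hard error", {
  pheno <- tiny_pheno_df()
  pheno[["snp:rs7903146"]] <- NULL
  pheno[["snp:rs4402960"]] <- NULL
  geno <- data.frame(subject_id = c("P1", "P2", "P9"),
                     rs7903146 = c("CC", "CT", "TT"),
                     stringsAsFactors = FALSE)
  gpath <- tempfile(fileext = ".csv")
  utils::write.csv(geno, gpath, row.names = FALSE)
  expect_error(load_cohort(write_tiny_pheno(pheno), gpath,
                           two_snp_annotation()), "P9")
})

test_that("VCF genotypes produce the same codes as equivalent CSV columns", {
  ann <- two_snp_annotation()
  df <- tiny_pheno_df()[1:3, ]
  calls <- as.matrix(df[, c("snp:rs7903146", "snp:rs4402960")])
  colnames(calls) <- ann$snp_id
  rownames(calls) <- df$subject_id
  vcf <- write_tiny_vcf(calls, ann)

  co_csv <- load_cohort(write_tiny_pheno(df), annotation = ann)
  pheno_only <- df
  pheno_only[["snp:rs7903146"]] <- NULL
  pheno_only[["snp:rs4402960"]] <- NULL
  co_vcf <- load_cohort(write_tiny_pheno(pheno_only), vcf, ann)

  for (snp in ann$snp_id) {
    a <- ann[ann$snp_id == snp, ]
    expect_equal(code_genotype(co_vcf[[paste0("snp:", snp)]], a, "additive"),
                 code_genotype(co_csv[[paste0("snp:", snp)]], a, "additive"))
  }
})

test_that("half calls and missing GT entries read from VCF as missing", {
  ann <- two_snp_annotation()
  calls <- matrix(c("CC", NA, "TT"), ncol = 1,
                  dimnames = list(paste0("P", 1:3), "rs7903146"))
  path <- write_tiny_vcf(calls, ann)
  lines <- readLines(path)
  lines[length(lines)] <- sub("1/1$", "./1", lines[length(lines)])
  writeLines(lines, path)
  g <- grstrata:::read_genotypes_vcf(path, ann)
  expect_equal(is.na(g[["snp:rs7903146"]]), c(FALSE, TRUE, TRUE))
})

test_that("genotype coding follows the declared genetic model", {
  ann <- two_snp_annotation()[1, ]  # C/T, risk T
  expect_equal(code_genotype("TT", ann, "additive"), 2)
  expect_equal(code_genotype(c("CT", "TC"), ann, "recessive"), c(0, 0))
  cod <- code_genotype(c("CC", "CT", "TT"), ann, "codominant")
  expect_equal(unname(cod[1, ]), c(0, 0))  # reference genotype
  expect_equal(unname(cod[2, ]), c(1, 0))
  expect_equal(unname(cod[3, ]), c(0, 1))
  expect_true(is.na(code_genotype(NA, ann, "additive")))
  expect_error(code_genotype("AG", ann, "additive"), "invalid genotype")
})

test_that("additive coding with the complementary risk allele reflects to 2 - code", {
  ann <- two_snp_annotation()[1, ]
  ann_flip <- ann
  ann_flip$risk_allele <- "C"
  set.seed(42)
  for (rep in 1:20) {
    calls <- sample(c("CC", "CT", "TC", "TT", NA), 30, replace = TRUE)
    a <- code_genotype(calls, ann, "additive")
    b <- code_genotype(calls, ann_flip, "additive")
    expect_equal(a, 2 - b)
  }
})

test_that("genotype frequencies match published counts and sum to 100", {
  f <- genotype_frequencies(as_genotype_counts(2770, 3249, 999))
  expect_equal(round(f$pct[["homref"]], 1), 39.5)
  expect_equal(round(f$allele_freq, 3), 0.374)
  # exact derivation: (3249 + 2*999) / (2*7018)
  expect_equal(f$allele_freq, (3249 + 2 * 999) / (2 * 7018))

  f0 <- genotype_frequencies(as_genotype_counts(10, 0, 0))
  expect_equal(unname(f0$pct), c(100, 0, 0))
  expect_equal(f0$allele_freq, 0)

  set.seed(7)
  for (rep in 1:25) {
    cts <- as_genotype_counts(sample(0:50, 1), sample(0:50, 1), sample(1:50, 1))
    expect_equal(sum(genotype_frequencies(cts)$pct), 100)
  }
  expect_error(genotype_frequencies(as_genotype_counts(0, 0, 0)), "zero")
})

test_that("hwe_test matches direct chi-square arithmetic", {
  # independent oracle: expected counts from the estimated allele frequency
  hwe_oracle <- function(aa, ab, bb) {
    n <- aa + ab + bb
    p <- (ab + 2 * bb) / (2 * n)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((c(aa, ab, bb) - e)^2 / e)
    list(stat = stat, p = pchisq(stat, 1, lower.tail = FALSE))
  }
  h <- hwe_test(as_genotype_counts(2770, 3249, 999))
  o <- hwe_oracle(2770, 3249, 999)
  expect_equal(h$statistic, o$stat)
  expect_equal(h$p_value, o$p)
  expect_gt(h$p_value, 0.05)

  # counts exactly at HWE proportions
  h0 <- hwe_test(as_genotype_counts(3600, 4800, 1600))  # p = 0.4
  expect_equal(h0$statistic, 0)

  # maximal disequilibrium
  expect_lt(hwe_test(as_genotype_counts(100, 0, 100))$p_value, 1e-10)

  # monomorphic SNP
  hm <- hwe_test(as_genotype_counts(50, 0, 0))
  expect_equal(hm$statistic, 0)
  expect_equal(hm$p_value, 1)
})

test_that("hwe_test has correct type-I error under true equilibrium", {
  set.seed(11)
  p <- 0.374; n <- 2000
  probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  rej <- vapply(1:1000, function(i) {
    g <- as.vector(rmultinom(1, n, probs))
    hwe_test(as_genotype_counts(g[1], g[2], g[3]))$p_value < 0.05
  }, logical(1))
  # rejection rate within 3 SD of nominal 0.05
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("obesity flag is recomputed from BMI, with conflicts reported", {
  df <- tiny_pheno_df()
  df$obesity <- c(TRUE, TRUE, TRUE, TRUE, FALSE)  # two conflicts with BMI
  expect_message(co <- as_cohort(df, two_snp_annotation()), "conflicted")
  expect_equal(co$obesity, co$bmi >= 30)
  expect_equal(attr(co, "log")$obesity_conflicts, 2)
})
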