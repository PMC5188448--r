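# Obesity-specific GRS: screening, partition, scoring, association, ROC.

test_that("screening ranks a stratum-confined SNP effect correctly", {
  set.seed(61)
  hits <- vapply(1:60, function(i) {
    co <- simulate_cohort(grs_pilot_config(n = 1000, or_per_allele = 1.4),
                          seed = 6000 + i)
    sc <- screen_snps(co, "rs4402960")  # effect confined to obese stratum
    sc$p_value[sc$stratum == "obese"] < sc$p_value[sc$stratum == "non-obese"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a monomorphic SNP is flagged without aborting the batch", {
  co <- simulate_cohort(grs_pilot_config(n = 400), seed = 63)
  co[["snp:rs2261181"]] <- "CC"
  sc <- screen_snps(co, c("rs7903146", "rs2261181"))
  expect_true(all(is.na(sc$or[sc$snp_id == "rs2261181"])))
  expect_true(all(nzchar(sc$note[sc$snp_id == "rs2261181"])))
  expect_true(all(!is.na(sc$or[sc$snp_id == "rs7903146"])))
})

test_that("partition assigns each SNP to its smaller-p stratum under the entry threshold", {
  # screen table reproducing the published partition pattern
  nob <- c("rs7903146", "rs12899811", "rs11634397", "rs11257655", "rs163184")
  ob <- c("rs6798189", "rs4402960", "rs3802177", "rs10842994", "rs2261181")
  tab <- do.call(rbind, lapply(c(nob, ob), function(s) {
    p_nob <- if (s %in% nob) 0.01 else 0.4
    p_ob <- if (s %in% ob) 0.02 else 0.3
    data.frame(snp_id = s, stratum = c("total", "non-obese", "obese"),
               p_value = c(0.05, p_nob, p_ob))
  }))
  part <- partition_snps(tab, alpha_in = 0.10)
  expect_setequal(part$nob_set, nob)
  expect_setequal(part$ob_set, ob)
  expect_equal(nrow(part$excluded), 0)

  # neither stratum reaches the threshold -> excluded
  tab2 <- data.frame(snp_id = "rsX", stratum = c("non-obese", "obese"),
                     p_value = c(0.5, 0.5))
  part2 <- partition_snps(tab2)
  expect_equal(part2$excluded$snp_id, "rsX")
  expect_length(part2$nob_set, 0)

  # significant only in the obese stratum -> obGRS
  tab3 <- data.frame(snp_id = "rsY", stratum = c("non-obese", "obese"),
                     p_value = c(0.8, 0.01))
  expect_equal(partition_snps(tab3)$ob_set, "rsY")

  # incomplete table is an error
  expect_error(partition_snps(data.frame(snp_id = "rsZ", stratum = "obese",
                                         p_value = 0.01)), "incomplete")
})

test_that("GRS is the unweighted risk-allele count with strict missingness", {
  co <- simulate_cohort(grs_pilot_config(n = 200), seed = 65)
  nob <- c("rs7903146", "rs12899811", "rs11634397", "rs11257655", "rs163184")
  ob <- c("rs6798189", "rs4402960", "rs3802177", "rs10842994", "rs2261181")
  s_nob <- compute_grs(co, nob)
  expect_true(all(s_nob >= 0 & s_nob <= 10))

  # additivity over disjoint sets and permutation invariance
  expect_equal(compute_grs(co, c(nob, ob)), s_nob + compute_grs(co, ob))
  expect_equal(compute_grs(co, sample(nob)), s_nob)

  # all-non-risk and all-risk extremes
  co2 <- co
  for (s in nob) co2[[paste0("snp:", s)]] <- co[[paste0("snp:", s)]][1]
  ann <- attr(co, "annotation")
  for (s in nob) {
    a <- ann[ann$snp_id == s, ]
    other <- setdiff(c(a$allele_a, a$allele_b), a$risk_allele)
    co2[[paste0("snp:", s)]] <- paste0(other, other)
  }
  expect_true(all(compute_grs(co2, nob) == 0))
  for (s in nob) {
    a <- ann[ann$snp_id == s, ]
    co2[[paste0("snp:", s)]] <- paste0(a$risk_allele, a$risk_allele)
  }
  expect_true(all(compute_grs(co2, nob) == 10))

  # a single missing member genotype blanks the score
  co3 <- co
  co3[["snp:rs7903146"]][5] <- NA
  expect_true(is.na(compute_grs(co3, nob)[5]))
})

test_that("GRS association is stronger in the stratum carrying the effect", {
  set.seed(67)
  nob <- c("rs7903146", "rs12899811", "rs11634397", "rs11257655", "rs163184")
  cfg <- grs_pilot_config(n = 1000, or_per_allele = 1.15)
  hits <- vapply(1:60, function(i) {
    co <- simulate_cohort(cfg, seed = 7000 + i)
    a <- grs_association(co, compute_grs(co, nob))
    a$p_value[a$stratum == "non-obese"] < a$p_value[a$stratum == "obese"]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("AUC equals exhaustive pair counting on small inputs", {
  # worked example: cases {3,5}, controls {2,3}
  r <- roc_auc(c(3, 5, 2, 3), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.875)

  pair_auc <- function(score, outcome) {
    cs <- score[outcome]; ct <- score[!outcome]
    mean(outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(4:50, 1)
    score <- sample(0:10, n, replace = TRUE)
    outcome <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    r <- roc_auc(score, outcome)
    expect_equal(r$auc, pair_auc(score, outcome), tolerance = 1e-12)
    # complement symmetry
    expect_equal(roc_auc(-score, outcome)$auc, 1 - r$auc, tolerance = 1e-12)
  }
})

test_that("AUC handles degenerate scores and rejects one-class outcomes", {
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  expect_equal(roc_auc(rep(3, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both outcome classes")
})

test_that("the Mann-Whitney p-value matches the tie-corrected normal approximation", {
  set.seed(73)
  score <- sample(0:8, 120, replace = TRUE)
  outcome <- runif(120) < 0.4
  r <- roc_auc(score, outcome)
  w <- suppressWarnings(stats::wilcox.test(score[outcome], score[!outcome],
                                           exact = FALSE, correct = FALSE))
  expect_equal(r$p_value, w$p.value, tolerance = 1e-10)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(74)
  score <- sample(0:10, 300, replace = TRUE)
  outcome <- runif(300) < plogis(-1 + 0.2 * score)
  r <- roc_auc(score, outcome)
  a <- as.numeric(pROC::auc(pROC::roc(outcome, score, quiet = TRUE,
                                      direction = "<")))
  expect_equal(r$auc, a, tolerance = 1e-10)
})

test_that("ROC curve is monotone and bootstrap CI brackets the estimate", {
  set.seed(75)
  score <- sample(0:10, 200, replace = TRUE)
  outcome <- runif(200) < plogis(-1 + 0.25 * score)
  r <- roc_auc(score, outcome, n_boot = 200, seed = 9)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
})
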