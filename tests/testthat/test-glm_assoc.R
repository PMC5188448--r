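# Logistic engine: cross-product oracles, interaction LRT, linear traits.

# subject-level expansion of a 2x2 table (exposed cases a, exposed
# non-cases b, unexposed cases c, unexposed non-cases d)
expand_2x2 <- function(a, b, c, d) {
  data.frame(y = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d)),
             x = rep(c(1, 1, 0, 0), c(a, b, c, d)))
}

test_that("logistic MLE on a 2x2 table equals the cross-product odds ratio", {
  d <- expand_2x2(20, 80, 10, 90)
  fit <- fit_logistic(d$y, d["x"])
  or <- exp(coef(fit)[["x"]])
  expect_rel_equal(or, (20 * 90) / (80 * 10))  # 2.25

  # closed-form Wald CI: exp(ln OR +/- 1.96 * sqrt(sum of 1/cells))
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  sm <- summary(fit)$coefficients
  ci <- exp(sm["x", "Estimate"] + qnorm(c(0.025, 0.975)) * sm["x", "Std. Error"])
  expect_equal(sm["x", "Std. Error"], se, tolerance = 1e-6)
  expect_equal(ci, exp(log(2.25) + qnorm(c(0.025, 0.975)) * se),
               tolerance = 1e-6)
})

test_that("cross-product equivalence holds over random non-degenerate tables", {
  set.seed(21)
  for (rep in 1:30) {
    cells <- sample(1:60, 4, replace = TRUE)
    d <- expand_2x2(cells[1], cells[2], cells[3], cells[4])
    fit <- fit_logistic(d$y, d["x"])
    expect_rel_equal(exp(coef(fit)[["x"]]),
                     (cells[1] * cells[4]) / (cells[2] * cells[3]), 1e-8)
  }
})

test_that("a balanced outcome-independent predictor gives OR = 1", {
  d <- expand_2x2(25, 75, 25, 75)
  expect_equal(exp(coef(fit_logistic(d$y, d["x"]))[["x"]]), 1, tolerance = 1e-9)
})

test_that("perfect separation and rank deficiency are flagged errors", {
  y <- rep(c(TRUE, FALSE), each = 20)
  x <- as.numeric(y)  # perfectly separating
  expect_error(fit_logistic(y, data.frame(x = x)), "separation")

  set.seed(3)
  y2 <- runif(50) < 0.5
  z <- rnorm(50)
  expect_error(fit_logistic(y2, data.frame(a = z, b = 2 * z)),
               "rank deficient")
  expect_error(fit_logistic(rep(TRUE, 30), data.frame(x = rnorm(30))),
               "single class")
})

test_that("interaction LRT equals brute-force likelihood maximisation on a 2x2x2", {
  # saturated cells: genotype (recessive) x modifier x outcome counts
  set.seed(9)
  n_cell <- matrix(c(40, 25, 30, 35, 20, 45, 50, 15), nrow = 4)
  g <- rep(c(0, 0, 1, 1), times = rowSums(n_cell))
  m <- rep(c(FALSE, TRUE, FALSE, TRUE), times = rowSums(n_cell))
  y <- unlist(lapply(1:4, function(i) rep(c(TRUE, FALSE), n_cell[i, ])))
  co <- toy_cohort(calls_from_codes(2 * g), t2d_prevalent = y, obesity = m)

  res <- interaction_test(co, "rs7903146", modifier = "obesity",
                          outcome = "t2d_prevalent", model = "model1",
                          coding = "recessive")

  loglik <- function(beta, X, y) {
    p <- plogis(drop(X %*% beta))
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  X_red <- cbind(1, g, m)
  X_full <- cbind(X_red, g * m)
  ll_red <- optim(rep(0, 3), function(b) -loglik(b, X_red, y),
                  method = "BFGS", control = list(reltol = 1e-14))$value
  ll_full <- optim(rep(0, 4), function(b) -loglik(b, X_full, y),
                   method = "BFGS", control = list(reltol = 1e-14))$value
  expect_equal(res$statistic, 2 * (ll_red - ll_full), tolerance = 1e-5)
  expect_equal(res$df, 1)
})

test_that("the LRT statistic is invariant to covariate scaling", {
  co <- suppressMessages(simulate_cohort(grs_pilot_config(n = 800), seed = 14))
  r1 <- interaction_test(co, "rs7903146", model = "model1")
  co2 <- co
  co2$age <- co2$age * 1000
  r2 <- interaction_test(co2, "rs7903146", model = "model1")
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-6)
  expect_gte(r1$statistic, 0)
})

test_that("stratified fits match the stratum effects implied by the full interaction model", {
  set.seed(31)
  n <- 1200
  g <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.45, 0.15))
  m <- runif(n) < 0.5
  y <- runif(n) < plogis(-0.3 + 0.5 * (g == 1) + 0.8 * (g == 2) -
                           0.4 * (g == 2) * m)
  co <- toy_cohort(calls_from_codes(g), t2d_prevalent = y, obesity = m)
  s <- stratified_or(co, "rs7903146", "t2d_prevalent", "obesity", "model1")

  # full-interaction model fitted directly (covariates are constant here)
  cm <- code_genotype(calls_from_codes(g), two_snp_annotation()[1, ], "codominant")
  fit <- fit_logistic(y, data.frame(het = cm[, 1], hom = cm[, 2], m = m,
                                    het_m = cm[, 1] * m, hom_m = cm[, 2] * m))
  b <- coef(fit)
  implied <- c(exp(b[["het"]]), exp(b[["hom"]]),
               exp(b[["het"]] + b[["het_m"]]), exp(b[["hom"]] + b[["hom_m"]]))
  expect_equal(s$or, unname(implied), tolerance = 1e-6)
})

test_that("stratified_or recovers a known stratum-specific effect pattern", {
  co <- simulate_cohort(seed = 77)
  s <- stratified_or(co, "rs7903146", "t2d_prevalent", "obesity", "model2")
  tt <- s[s$contrast == "TT vs CC", ]
  # generating odds ratios 2.26 (non-obese) and 1.53 (obese)
  expect_true(tt$ci_low[tt$stratum == "non-obese"] < 2.26 &&
                2.26 < tt$ci_high[tt$stratum == "non-obese"])
  expect_true(tt$ci_low[tt$stratum == "obese"] < 1.53 &&
                1.53 < tt$ci_high[tt$stratum == "obese"])
  expect_lt(attr(s, "p_interaction"), 0.05)
  expect_lt(attr(s, "global_p")[["non-obese"]], 1e-10)
})

test_that("a stratum with degenerate outcome is reported undefined, not fatal", {
  g <- sample(0:2, 80, replace = TRUE)
  y <- c(rep(FALSE, 40), runif(40) < 0.5)   # prevalence 0 in non-obese
  m <- rep(c(FALSE, TRUE), each = 40)
  co <- toy_cohort(calls_from_codes(g), t2d_prevalent = y, obesity = m)
  expect_warning(
    expect_warning(s <- stratified_or(co, "rs7903146", "t2d_prevalent",
                                      "obesity", "model1"), "non-obese"),
    "interaction test undefined")
  expect_true(all(is.na(s$or[s$stratum == "non-obese"])))
  expect_true(any(!is.na(s$or[s$stratum == "obese"])))
})

test_that("interaction p-values are uniform under the null", {
  set.seed(55)
  pvals <- vapply(1:300, function(i) {
    n <- 500
    g <- sample(0:2, n, replace = TRUE, prob = c(0.39, 0.47, 0.14))
    m <- runif(n) < 0.47
    y <- runif(n) < plogis(-0.1 + 0.3 * g)   # no interaction
    co <- toy_cohort(calls_from_codes(g), t2d_prevalent = y, obesity = m)
    interaction_test(co, "rs7903146", model = "model1")$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("adjusted genotype means equal raw means on balanced no-covariate data", {
  set.seed(8)
  g <- rep(0:2, each = 60)
  t2d <- rep(c(FALSE, TRUE), 90)
  bmi <- 28 + 0.5 * g + rnorm(180)
  co <- toy_cohort(calls_from_codes(g), t2d_prevalent = t2d)
  co$bmi <- bmi
  co$obesity <- co$bmi >= 30
  res <- fit_linear_trait(co, "rs7903146", "bmi", "t2d_prevalent", "model1")
  for (lev in c("non-T2D", "T2D")) {
    sel <- if (lev == "T2D") t2d else !t2d
    raw <- tapply(bmi[sel], g[sel], mean)
    adj <- res$adjusted_means$mean[res$adjusted_means$stratum == lev]
    expect_equal(adj, as.vector(raw), tolerance = 1e-8)
  }
})

test_that("a T2D-confined genotype effect on BMI is detected as interaction", {
  set.seed(19)
  detected <- vapply(1:60, function(i) {
    n <- 7018
    g <- sample(0:2, n, replace = TRUE, prob = c(0.39, 0.47, 0.14))
    t2d <- runif(n) < 0.486
    bmi <- 30 - 0.5 * g * t2d + rnorm(n, sd = 3.8)
    co <- toy_cohort(calls_from_codes(g), t2d_prevalent = t2d)
    co$bmi <- bmi
    co$obesity <- co$bmi >= 30
    fit_linear_trait(co, "rs7903146", "bmi", "t2d_prevalent",
                     "model1")$p_interaction < 0.05
  }, logical(1))
  expect_gt(mean(detected), 0.8)
})
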