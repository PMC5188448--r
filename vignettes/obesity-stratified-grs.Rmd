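---
title: "Obesity-stratified genetic association and obesity-specific genetic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Obesity-stratified genetic association and obesity-specific genetic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grstrata)
```

# The scientific problem

The TCF7L2-rs7903146 C>T polymorphism is the strongest common genetic
determinant of type 2 diabetes (T2D), yet its effect is not homogeneous:
several cohorts have reported that the association is markedly stronger
in non-obese than in obese individuals.  If genetic effects on T2D are
heterogeneous by obesity, then a conventional genetic risk score (GRS)
that simply sums risk alleles over loci selected from unstratified
genome-wide scans will dilute stratum-specific signal.  `grstrata`
implements the full analysis cycle around this question:

1. **Baseline (prevalence) analysis** — obesity-stratified logistic
   regression of prevalent T2D on genotype, with a formal genotype ×
   obesity interaction test; the mirror analysis (T2D-stratified models
   of obesity, and of continuous traits such as BMI) probes the reverse
   interaction.
2. **Incidence analysis** — person-years, crude rates per 1000
   person-years, obesity-stratified Cox models, Kaplan–Meier
   one-minus-survival curves, in baseline-T2D-free subjects.
3. **Predictive value** — sensitivity/specificity/PPV/NPV of the
   recessive TT-carrier "test" and ROC/AUC of the additive genotype or
   of a GRS, by obesity stratum.
4. **Obesity-specific GRS** — the central procedure: screen candidate
   T2D SNPs for association within each obesity stratum, partition them
   into a non-obese-specific score (nobGRS) and an obese-specific score
   (obGRS), sum risk alleles unweighted (0–2 per SNP), and evaluate each
   score's AUC in each stratum.
5. **Longitudinal BMI** — a repeated-measures model testing whether the
   genotype effect on BMI trajectories is confined to T2D subjects.
6. **Synthetic cohort generator and Monte-Carlo power** — so that every
   stage is exercisable and testable without individual-level study
   data, which are not publicly deposited.

# Models and their assumptions

## Genotype handling

Genotypes enter as two-character calls (e.g. `"CT"`) relative to a
declared allele pair, from inline CSV columns, a genotype CSV, or a
VCFv4.2 file (GT field, diploid; half calls are treated as missing).
Coding is relative to the declared *risk* allele: additive (0/1/2),
recessive (homozygous risk vs carriers of the common allele), or
codominant (two indicator contrasts against the homozygous non-risk
reference).  Missing genotypes are handled complete-case per analysis,
so each model reports its own n.

The Hardy–Weinberg check is the 1-df Pearson goodness-of-fit chi-square
against expected genotype proportions computed from the estimated
allele frequency; it gates downstream analysis as a genotyping quality
control.  Obesity is always recomputed from BMI (BMI ≥ 30 kg/m²),
overriding any supplied flag, so there is a single source of truth for
stratification.

## Regression models

Two covariate sets are used throughout.  *Model 1* adjusts for sex, age
and recruitment centre (entered as a categorical indicator set), plus
the intervention arm in time-to-event models; *Model 2* adds total
energy intake, Mediterranean-diet adherence, alcohol intake, smoking,
physical activity, dyslipidemia and hypertension.  Continuous
covariates enter untransformed; smoking and drinking as current-status
indicators.  Covariates fixed within a stratum (e.g. obesity inside an
obesity stratum) drop out of that stratum's design automatically.

Logistic models are fitted by iteratively reweighted least squares
(relative deviance tolerance 1e-10, at most 100 iterations), with hard
errors for rank-deficient designs (naming the collinear columns) and
for perfect separation.  The "global polymorphism" p-value is a
likelihood-ratio test of all genotype contrasts jointly; the
interaction p is a likelihood-ratio test of the genotype × modifier
product terms, with degrees of freedom equal to the number of genotype
contrasts (2 codominant, 1 additive/recessive).  The LRT was chosen
over the Wald test because it yields a single well-defined p-value for
the multi-degree-of-freedom codominant case.

Cox models use the partial likelihood with Efron tie handling (the
standard modern default; the original analysis software is silent on
ties) and time since enrolment as the time axis.  Deaths and losses are
administrative censorings.  Recessive-model hazard ratios are reported
alongside the codominant contrasts because the incident-T2D effect is
empirically recessive-like.

Adjusted genotype means for continuous traits (and for the BMI
trajectory model) are computed by marginal standardisation: model
predictions averaged over the observed covariate distribution.  This
reproduces raw genotype means exactly on balanced covariate-free data.

## ROC/AUC

AUC is computed by the rank (Mann–Whitney) construction with ties
counted one half, on the raw integer score without covariate
adjustment — the score itself is the diagnostic instrument being
evaluated.  The p-value against AUC = 0.5 uses the tie-corrected normal
approximation to the Mann–Whitney statistic.  A seeded bootstrap
(2000 resamples by default in the pipeline) supplies percentile
confidence intervals, which the AUC p-value alone does not.

## GRS partition rule

The screening step fits, per SNP, an additive logistic model of
prevalent T2D adjusted for age, sex and (in the pooled model) obesity,
in the total sample and within each obesity stratum.  The partition
rule is deliberately explicit and auditable: a SNP joins the score of
the stratum where its screening p-value is smaller, *provided* that
p-value is below an entry threshold `alpha_in` (default 0.10, capturing
"significant or near-significant" stratum associations); otherwise it
is excluded with a recorded reason.  Scores are plain unweighted
risk-allele counts; a subject missing any member genotype receives a
missing score rather than a prorated one, preserving the integer count
interpretation.

With ten SNPs, per-allele stratum odds ratios around 1.15 and a
single-centre subsample of n ≈ 1000, the screen is intentionally noisy:
individual SNPs frequently miss the 0.10 threshold or land in the
"wrong" stratum in any one realisation.  That is a property of the
procedure at pilot scale, and the package reports the partition audit
rather than hiding it.  The headline property — each score
discriminates better in its own stratum — is a statement about the
*median* behaviour over repeated cohorts, and that is how the test
suite checks it.

## Repeated-measures BMI

"Repeated-measures ANCOVA" is implemented as a linear mixed model with
a subject-level random intercept, which imposes the same
compound-symmetry covariance as the classical procedure.  The
between-subject genotype effect and the genotype × T2D interaction are
tested by Type-III F tests with Satterthwaite degrees of freedom
(`lmerTest`), not by a likelihood-ratio chi-square: on balanced
two-group data this reproduces the two-sample t-test on per-subject
means exactly, which an asymptotic LRT does not, and it is the closer
analogue of the original F-based ANCOVA.  Panels are strictly
complete-case over the chosen window (baseline through year 4 or 6),
mirroring the "complete data at every visit" inclusion rule.

# The synthetic cohort generator

Because no individual-level data are deposited, the generator is a
first-class, tested module whose defaults encode the study conditions
reported for the source cohort:

| quantity | default | provenance |
|---|---|---|
| subjects | 7018 | study n |
| TCF7L2 risk-allele frequency | 0.374 | derived from genotype counts 2770/3249/999 |
| obesity prevalence | 3279/7018 = 46.7% | baseline stratum sizes |
| prevalent T2D | ≈48.6% overall; stratum targets 0.488 (non-obese) / 0.484 (obese) | overall 3411/7018; stratum split derived from the incidence-table margins (1693 obese of 3597 T2D-free) |
| prevalence ORs (codominant, CT/TT) | 1.78/2.26 non-obese; 1.27/1.53 obese | fully adjusted stratified estimates |
| baseline incidence rates | 11.6 (non-obese CC), 17.7 (obese CC) per 1000 PY | crude CC-cell rates |
| incidence HRs (CT/TT) | 1.14/1.81 non-obese; 1.05/1.01 obese | fully adjusted stratified estimates |
| accrual / censoring | entry uniform over 6.2 y, administrative censoring at 8.7 y | accrual window Oct 2003–Dec 2009 with follow-up to mid-2012; reproduces median follow-up ≈ 5.7 y and maximum 8.7 y |
| BMI | N(30.0, 3.8) truncated consistently around 30 | baseline mean ± SD |
| BMI trajectory | −0.4 kg/m² per risk allele in T2D subjects only; drift 0.02/y; within-subject SD 0.8; annual retention 0.87 | T2D-confined inverse association pattern |

Genotypes are drawn under Hardy–Weinberg equilibrium at independent
loci (linkage disequilibrium set to zero — the analysis treats loci
additively and independently, and LD hooks would only matter for
weighted scores, which are out of scope).  Prevalent T2D comes from a
stratum-specific logistic model whose intercepts are calibrated
analytically (exact convolution of per-locus effect distributions, then
root-finding) so the marginal stratum prevalences hit their targets.
Incident T2D uses exponential event times under stratum × genotype
hazards with uniform staggered entry and administrative censoring;
prevalent cases contribute no follow-up.  Covariates are generated
independently of genotype (no confounding) with realistic marginal
distributions; a genotype-confounded mode was considered and left as
future work since every adjusted analysis is already exercised by the
covariate machinery.

Risk-allele frequencies for the nine non-TCF7L2 loci, and their risk
alleles, are not printed in the source tables; the defaults use
published values where established and plausible European-population
values otherwise, chosen once.  Their per-allele prevalence effects
default to OR 1.15 confined to the stratum whose score each SNP
belongs to, mirroring the stratum-confined pattern the GRS procedure
is designed to detect.

What the generator does *not* emulate: population structure and
admixture, linkage disequilibrium, genotype–covariate confounding, the
dietary-intervention effect (the arm is an adjustment covariate only),
and informative (non-administrative) censoring.  Tests that pass on
these cohorts therefore demonstrate the correctness and calibration of
the estimators under the stated generative model, not robustness to
those real-data complications.

## Monte-Carlo power

`estimate_power()` simulates T2D-free cohorts (default n = 3607 with
the baseline hazard calibrated analytically so the expected event count
is 312) in which the homozygous-risk hazard ratio equals the requested
interaction effect in non-obese subjects and 1 in obese subjects, fits
the Cox model with genotype, obesity and their product, and tests the
product term by a 1-df likelihood ratio.  At an interaction hazard
ratio of 1.75, homozygote frequency 11.8% and obesity prevalence 47%,
the Monte-Carlo power at alpha = 0.05 is ≈ 0.40–0.45.  This is an
intrinsic property of the design: the variance of the interaction
log-HR is approximately the sum of reciprocal event counts over the
four exposure × stratum cells, and with only ≈ 50 events among
homozygotes the standard error (≈ 0.32) nearly equals the effect
(ln 1.75 ≈ 0.56).  A stratum-specific *association* of HR 1.75, by
contrast, is detected with power ≈ 0.9 at this design — the
distinction matters when reading published power statements for
interaction analyses.

# Numerical choices and degenerate inputs

* Logistic convergence: relative deviance change < 1e-10, ≤ 100
  iterations; separation detected by diverging linear predictors with
  inflated coefficients and reported as an error rather than returning
  meaningless estimates.
* Strata in which a fit is undefined (empty genotype cell, one-class
  outcome, monomorphic SNP) are reported as `NA` rows with a warning or
  note; batch operations (SNP screening) never abort on a single bad
  SNP.
* Predictive values use exact Clopper–Pearson intervals; the 2×2
  association p switches from Pearson chi-square to Fisher's exact test
  when any expected cell is below 5, and says so.
* Reported rates follow the field's rounding conventions (rates to one
  decimal, ORs/HRs/AUC to two–three decimals) only at presentation;
  all computation is done unrounded.
* Problem sizes in the test suite: parameter-recovery and calibration
  checks use 200–300 replicates at the study's own sample sizes
  (n = 7018 baseline, n = 3607 incidence); the GRS headline property
  uses 200 replicates of the n = 1000 pilot configuration; the
  longitudinal power check uses 40 replicates at n = 3141.  These sizes
  give Monte-Carlo standard errors comfortably below the margins being
  asserted.

# Known limitations

* The partition procedure is evaluated on apparent (in-sample) AUC, as
  in the source analysis; cross-validated AUC and weighted or penalised
  scores are explicitly out of scope.
* No Firth correction or mixed-effects logistic models; very sparse
  strata simply report as undefined.
* Proportional-hazards diagnostics beyond the reported models are not
  included; the generator's exponential hazards satisfy
  proportionality by construction.
* The body-fat estimating equation used at baseline in the source
  study is not printed there; body-fat analyses run on any supplied
  `body_fat_pct` column, and the simulator does not generate one.

# Session info

```{r}
sessionInfo()
```
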