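# Internal helpers shared across modules.

# Restore the caller's RNG state on exit so seeded simulation calls do not
# perturb the global random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Likelihood-ratio test between two nested fits carrying logLik methods.
lrt_pvalue <- function(fit_reduced, fit_full, df) {
  stat <- as.numeric(2 * (stats::logLik(fit_full) - stats::logLik(fit_reduced)))
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

# Wald 95% CI on the exp scale for a named coefficient.
wald_exp_ci <- function(beta, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(exp(beta - z * se), exp(beta + z * se))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Drop columns that are constant (after NA removal) from a model data frame,
# returning the names removed.  Strata fix some adjustment covariates (e.g.
# obesity within an obesity stratum); fitting proceeds without them.
drop_constant_columns <- function(df, protect = character()) {
  drop <- vapply(names(df), function(nm) {
    if (nm %in% protect) return(FALSE)
    x <- df[[nm]]
    x <- x[!is.na(x)]
    length(unique(x)) < 2L
  }, logical(1))
  list(data = df[, !drop, drop = FALSE], dropped = names(df)[drop])
}
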