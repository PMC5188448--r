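# Pipeline orchestration: simulate or load a cohort, then run the
# requested analysis stages in dependency order, exporting tidy TSV/JSON
# reports and a run manifest.

.ALL_STAGES <- c("simulate", "associate", "incidence", "grs", "diagnostics",
                 "longitudinal")

#' Run the full analysis pipeline
#'
#' Executes the requested stages against a simulated or loaded cohort:
#' `associate` (genotype frequencies, Hardy-Weinberg check, obesity- and
#' T2D-stratified odds ratios with interaction p-values), `incidence`
#' (person-time, crude rates, stratified Cox models, Kaplan-Meier
#' exports), `grs` (screen, partition audit, scores, association, ROC
#' exports), `diagnostics` (recessive-model predictive values) and
#' `longitudinal` (repeated-measures BMI).  A failing stage aborts only
#' its dependents; the manifest records partial completion.
#'
#' @param config a configuration list or path to a YAML file.  Keys:
#'   `seed`; `simulate` (logical) with optional `sim` overrides (e.g.
#'   `n`); or `input` with `phenotypes` / `genotypes` / `annotation` /
#'   `bmi_long` paths; `focal_snp` (default rs7903146); `grs_snps`;
#'   `alpha_in`; `stages`.
#' @param out_dir output directory (created if needed).
#' @param seed overrides `config$seed` when given.
#' @return invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = "pipeline_out",
                         seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- seed %||% config$seed %||% 1L
  stages <- config$stages %||% .ALL_STAGES
  bad <- setdiff(stages, .ALL_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  focal <- config$focal_snp %||% "rs7903146"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  write_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    path
  }

  sim_cfg <- default_sim_config()
  sim_cfg[names(config$sim %||% list())] <- config$sim
  annotation <- if (!is.null(config$input$annotation))
    read_snp_annotation(config$input$annotation) else default_annotation()

  results <- list(); outputs <- character(); status <- character()
  failed <- character()
  run_stage <- function(name, deps, fun) {
    if (!name %in% stages) { status[name] <<- "skipped"; return(invisible()) }
    if (any(deps %in% failed)) {
      status[name] <<- paste("aborted: dependency failed");
      failed <<- c(failed, name); return(invisible())
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      warning("stage '", name, "' failed: ", conditionMessage(res), call. = FALSE)
      status[name] <<- paste("failed:", conditionMessage(res))
      failed <<- c(failed, name)
    } else {
      results[[name]] <<- res
      status[name] <<- "ok"
    }
  }

  # --- cohort: simulate or load -------------------------------------------
  cohort <- NULL; bmi_long <- NULL
  if (isTRUE(config$simulate) || is.null(config$input)) {
    grs_snps <- config$grs_snps %||% names(sim_cfg$risk_freq)
    missing_snps <- setdiff(grs_snps, names(sim_cfg$risk_freq))
    if ("grs" %in% stages && length(missing_snps))
      stop("GRS stage requested but no genotypes configured for: ",
           paste(missing_snps, collapse = ", "))
    run_stage("simulate", character(), function() {
      cohort <<- simulate_cohort(sim_cfg, seed = seed, annotation = annotation)
      bmi_long <<- simulate_bmi_panel(cohort, sim_cfg, seed = seed + 1L,
                                      snp = focal)
      outputs <<- c(outputs, write_tsv(as.data.frame(cohort), "cohort.tsv"),
                    write_tsv(bmi_long, "bmi_long.tsv"))
      list(n = nrow(cohort))
    })
  } else {
    status["simulate"] <- "skipped"
    cohort <- load_cohort(config$input$phenotypes, config$input$genotypes,
                          annotation)
    if (!is.null(config$input$bmi_long))
      bmi_long <- read_table_auto(config$input$bmi_long)
    grs_snps <- config$grs_snps %||%
      annotation$snp_id[geno_col(annotation$snp_id) %in% names(cohort)]
    missing_snps <- setdiff(geno_col(grs_snps), names(cohort))
    if ("grs" %in% stages && length(missing_snps))
      stop("GRS stage requested but cohort lacks genotype column(s): ",
           paste(missing_snps, collapse = ", "))
  }
  if (is.null(cohort)) stop("no cohort available: simulation failed")
  ann_focal <- snp_annotation_row(annotation, focal)

  # --- baseline associations ----------------------------------------------
  run_stage("associate", "simulate", function() {
    counts <- genotype_counts(cohort_calls(cohort, focal), ann_focal)
    freq <- genotype_frequencies(counts)
    hwe <- hwe_test(counts)
    t2d_by_ob <- lapply(c(m1 = "model1", m2 = "model2"), function(m)
      stratified_or(cohort, focal, "t2d_prevalent", "obesity", m))
    ob_by_t2d <- lapply(c(m1 = "model1", m2 = "model2"), function(m)
      stratified_or(cohort, focal, "obesity", "t2d_prevalent", m))
    bmi_trait <- fit_linear_trait(cohort, focal, "bmi", "t2d_prevalent",
                                  "model2")
    flatten <- function(lst) do.call(rbind, lapply(lst, function(x) {
      x$global_p <- attr(x, "global_p")[x$stratum]
      x$p_interaction <- attr(x, "p_interaction")
      x
    }))
    outputs <<- c(outputs,
                  write_tsv(flatten(t2d_by_ob), "t2d_by_obesity_or.tsv"),
                  write_tsv(flatten(ob_by_t2d), "obesity_by_t2d_or.tsv"),
                  write_tsv(bmi_trait$adjusted_means, "bmi_adjusted_means.tsv"))
    list(genotype_pct = freq$pct, allele_freq = freq$allele_freq,
         hwe = hwe, t2d_by_obesity = t2d_by_ob, obesity_by_t2d = ob_by_t2d,
         bmi_trait = bmi_trait)
  })

  # --- incidence ----------------------------------------------------------
  run_stage("incidence", "simulate", function() {
    cox <- lapply(c(m1 = "model1", m2 = "model2"), function(m)
      cox_stratified_and_interaction(cohort, focal, "obesity", m))
    inc <- incidence_subset(cohort)
    g <- code_genotype(inc[[geno_col(focal)]], ann_focal, "additive")
    km <- km_one_minus_survival(
      inc$followup_years, inc$t2d_incident,
      paste(ifelse(inc$obesity, "obese", "non-obese"), g, sep = ":"))
    outputs <<- c(outputs, write_tsv(cox$m2$cells, "incidence_cells.tsv"),
                  write_tsv(rbind(cox$m1$hr, cox$m2$hr), "incidence_hr.tsv"),
                  write_tsv(km, "km_curves.tsv"))
    list(models = cox, km = km)
  })

  # --- GRS ----------------------------------------------------------------
  run_stage("grs", "simulate", function() {
    screen <- screen_snps(cohort, grs_snps)
    part <- partition_snps(screen, alpha_in = config$alpha_in %||% 0.10)
    audit <- list(rule = part$rule, alpha_in = part$alpha_in,
                  nob_set = part$nob_set, ob_set = part$ob_set,
                  excluded = part$excluded, screen = screen)
    audit_path <- file.path(out_dir, "grs_partition_audit.json")
    jsonlite::write_json(audit, audit_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    rocs <- list(); assoc <- list()
    for (set_name in c("nob_set", "ob_set")) {
      snp_set <- part[[set_name]]
      if (!length(snp_set)) next
      grs_name <- if (set_name == "nob_set") "nobGRS" else "obGRS"
      score <- compute_grs(cohort, snp_set)
      assoc[[grs_name]] <- grs_association(cohort, score)
      for (strat in c("non-obese", "obese")) {
        keep <- if (strat == "obese") cohort$obesity else !cohort$obesity
        roc <- roc_auc(score[keep], cohort$t2d_prevalent[keep],
                       n_boot = 2000, seed = seed + 7L)
        rocs[[paste(grs_name, strat, sep = "|")]] <- roc
        outputs <<- c(outputs, write_tsv(
          roc$curve, paste0("roc_", grs_name, "_", gsub("-", "", strat), ".tsv")))
      }
    }
    outputs <<- c(outputs, audit_path,
                  write_tsv(do.call(rbind, Map(function(nm, a) {
                    a$grs <- nm; a
                  }, names(assoc), assoc)), "grs_association.tsv"))
    list(screen = screen, partition = part, association = assoc, roc = rocs)
  })

  # --- diagnostics --------------------------------------------------------
  run_stage("diagnostics", "simulate", function() {
    inc <- incidence_subset(cohort)
    rec <- code_genotype(inc[[geno_col(focal)]], ann_focal, "recessive")
    res <- lapply(c("non-obese", "obese"), function(strat) {
      keep <- if (strat == "obese") inc$obesity else !inc$obesity
      predictive_values(rec[keep] == 1, inc$t2d_incident[keep], strat)
    })
    outputs <<- c(outputs, write_tsv(do.call(rbind, lapply(res, diagnostic_row)),
                                     "predictive_values.tsv"))
    res
  })

  # --- longitudinal -------------------------------------------------------
  run_stage("longitudinal", "simulate", function() {
    if (is.null(bmi_long)) stop("no repeated-measures BMI table available")
    panel <- build_panel(cohort, bmi_long, window = 4, snp = focal)
    fit <- fit_repeated_bmi(panel)
    outputs <<- c(outputs, write_tsv(fit$adjusted_means,
                                     "bmi_trajectories.tsv"))
    list(p_genotype = fit$p_genotype, p_interaction = fit$p_interaction,
         adjusted_means = fit$adjusted_means,
         retention = attr(panel, "retention"))
  })

  # --- machine-readable summary -------------------------------------------
  summary <- list()
  if (!is.null(results$associate)) {
    a <- results$associate
    summary$allele_freq <- a$allele_freq
    summary$hwe_p <- a$hwe$p_value
    summary$p_interaction_t2d_by_obesity <-
      unname(attr(a$t2d_by_obesity$m2, "p_interaction"))
    summary$p_interaction_obesity_by_t2d <-
      unname(attr(a$obesity_by_t2d$m2, "p_interaction"))
  }
  if (!is.null(results$incidence))
    summary$p_interaction_incidence <- results$incidence$models$m2$p_interaction
  if (!is.null(results$grs))
    summary$auc <- lapply(results$grs$roc, function(r) r$auc)
  if (!is.null(results$diagnostics))
    summary$predictive_p <- lapply(results$diagnostics, function(d) d$p_value)
  if (!is.null(results$longitudinal))
    summary$p_interaction_bmi_trajectory <-
      unname(results$longitudinal$p_interaction)
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, summary_path)

  # --- manifest -----------------------------------------------------------
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("grstrata")),
    seed = seed, config_md5 = unname(tools::md5sum(tmp)),
    stage_status = as.list(status),
    n_subjects = nrow(cohort),
    outputs = basename(outputs),
    output_md5 = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                         basename(outputs))))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}
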