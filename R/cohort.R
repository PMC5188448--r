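# Cohort loading and validation.
#
# The universal input is a subject-level table (one row per subject) with
# phenotypes, follow-up and lifestyle covariates, plus genotype calls held
# either inline (columns named "snp:<rsid>") or in a VCF / genotype CSV
# keyed by subject id.

.MANDATORY_COLS <- c("subject_id", "age", "sex", "center", "arm", "bmi",
                     "t2d_prevalent", "followup_years", "t2d_incident")
.COVARIATE_COLS <- c("energy", "meddiet", "alcohol", "smoking", "physact",
                     "dyslipidemia", "hypertension")

geno_col <- function(snp_id) paste0("snp:", snp_id)

#' Read a SNP annotation table
#'
#' @param path CSV with columns `snp_id`, `gene_label`, `allele_a`,
#'   `allele_b`, `risk_allele`.
#' @return data.frame of class `snp_annotation`.
#' @export
read_snp_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("snp_id", "gene_label", "allele_a", "allele_b", "risk_allele")
  missing <- setdiff(needed, names(ann))
  if (length(missing))
    stop("annotation file is missing column(s): ", paste(missing, collapse = ", "))
  bad <- with(ann, risk_allele != allele_a & risk_allele != allele_b)
  if (any(bad))
    stop("risk allele not among declared alleles for: ",
         paste(ann$snp_id[bad], collapse = ", "))
  class(ann) <- c("snp_annotation", "data.frame")
  ann
}

#' Default 10-SNP annotation
#'
#' The ten type-2-diabetes SNPs analysed by the package: TCF7L2-rs7903146
#' plus nine further T2D loci.  Alleles and risk alleles follow published
#' T2D association reports; this table is the default annotation consumed
#' by the simulator and the pipeline.
#'
#' @return a `snp_annotation` data.frame with one row per SNP.
#' @export
default_annotation <- function() {
  ann <- data.frame(
    snp_id = c("rs7903146", "rs12899811", "rs11634397", "rs11257655",
               "rs163184", "rs6798189", "rs4402960", "rs3802177",
               "rs10842994", "rs2261181"),
    gene_label = c("TCF7L2", "PRC1", "ZFAND6", "CDC123_CAMK1D", "KCNQ1",
                   "ADCY5", "IGF2BP2", "SLC30A8", "KLHDC5", "HMGA2"),
    allele_a = c("C", "A", "G", "C", "T", "A", "G", "G", "C", "C"),
    allele_b = c("T", "G", "A", "T", "G", "G", "T", "A", "T", "T"),
    risk_allele = c("T", "G", "G", "T", "G", "G", "T", "G", "C", "T"),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("snp_annotation", "data.frame")
  ann
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

# Read genotype calls from a VCF (v4.2, GT field, diploid, unphased
# accepted).  Half calls and missing GT become NA.  Returns a data.frame
# with subject_id plus one "snp:<rsid>" column per annotated SNP present.
read_genotypes_vcf <- function(path, annotation) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  out <- data.frame(subject_id = colnames(gt), stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (i in seq_len(nrow(fix))) {
    rsid <- fix[i, "ID"]
    if (!rsid %in% annotation$snp_id) next
    alleles <- c(fix[i, "REF"], fix[i, "ALT"])
    g <- gt[i, ]
    g <- gsub("\\|", "/", g)
    parts <- strsplit(g, "/", fixed = TRUE)
    calls <- vapply(parts, function(p) {
      if (length(p) != 2 || any(is.na(p)) || any(p == "."))
        return(NA_character_)
      idx <- as.integer(p) + 1L
      if (any(is.na(idx)) || any(idx > length(alleles))) return(NA_character_)
      paste0(alleles[idx[1]], alleles[idx[2]])
    }, character(1))
    calls[is.na(g)] <- NA_character_
    out[[geno_col(rsid)]] <- unname(calls)
  }
  out
}

#' Load and validate a cohort
#'
#' Reads a subject-level phenotype table, optionally merges genotypes
#' from a separate source (genotype CSV or VCF), recomputes the obesity
#' flag from BMI (obesity defined as BMI >= 30 kg/m^2, overriding any
#' supplied flag), and drops rows failing validation (complete-case on
#' the mandatory phenotype fields).  Dropped-row and flag-conflict
#' counts are recorded in the `log` attribute.
#'
#' @param phenotype_table path to CSV/TSV with the documented header
#'   (`subject_id`, `age`, `sex`, `center`, `arm`, `bmi`,
#'   `t2d_prevalent`, `followup_years`, `t2d_incident`, optional
#'   lifestyle covariate columns and optional inline genotype columns
#'   `snp:<rsid>`).
#' @param genotype_source optional path to a genotype CSV (columns
#'   `subject_id` plus `<rsid>` or `snp:<rsid>`) or a VCF whose sample
#'   names match subject ids.
#' @param annotation a `snp_annotation` data.frame.
#' @return a `grs_cohort` data.frame; attributes `annotation` and `log`.
#' @export
load_cohort <- function(phenotype_table, genotype_source = NULL,
                        annotation = default_annotation()) {
  pheno <- read_table_auto(phenotype_table)
  missing <- setdiff(.MANDATORY_COLS, names(pheno))
  if (length(missing))
    stop("phenotype table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))

  if (!is.null(genotype_source)) {
    geno <- if (grepl("\\.vcf(\\.gz)?$", genotype_source, ignore.case = TRUE))
      read_genotypes_vcf(genotype_source, annotation)
    else {
      g <- read_table_auto(genotype_source)
      if (!"subject_id" %in% names(g))
        stop("genotype table is missing mandatory column(s): subject_id")
      bare <- intersect(names(g), annotation$snp_id)
      names(g)[match(bare, names(g))] <- geno_col(bare)
      g
    }
    unmatched <- setdiff(geno$subject_id, pheno$subject_id)
    if (length(unmatched))
      stop("subject id(s) in genotype source absent from phenotype table: ",
           paste(unmatched, collapse = ", "))
    pheno <- merge(pheno, geno, by = "subject_id", all.x = TRUE, sort = FALSE)
  }
  as_cohort(pheno, annotation)
}

#' Construct a cohort from an in-memory data frame
#'
#' Applies the same validation, type coercion and obesity-flag
#' recomputation as [load_cohort()].
#'
#' @param df subject-level data.frame with the documented columns.
#' @param annotation a `snp_annotation` data.frame.
#' @return a `grs_cohort` data.frame.
#' @export
as_cohort <- function(df, annotation = default_annotation()) {
  n_in <- nrow(df)
  for (col in c("t2d_prevalent", "t2d_incident", "smoking", "dyslipidemia",
                "hypertension")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df$sex <- factor(df$sex, levels = c("male", "female"))
  df$center <- factor(df$center)
  df$arm <- factor(df$arm)

  ok <- !is.na(df$subject_id) & !is.na(df$age) & !is.na(df$sex) &
    !is.na(df$bmi) & !is.na(df$t2d_prevalent)
  # incident flag only meaningful for baseline-T2D-free subjects
  bad_incident <- !is.na(df$t2d_incident) & df$t2d_incident &
    !is.na(df$t2d_prevalent) & df$t2d_prevalent
  neg_fu <- !is.na(df$followup_years) & df$followup_years < 0
  ok <- ok & !bad_incident & !neg_fu

  conflicts <- 0L
  obesity_new <- df$bmi >= 30
  if ("obesity" %in% names(df)) {
    old <- as.logical(df$obesity)
    conflicts <- sum(!is.na(old) & !is.na(obesity_new) & old != obesity_new)
    if (conflicts > 0)
      message(conflicts, " supplied obesity flag(s) conflicted with BMI >= 30; ",
              "recomputed from BMI")
  }
  df$obesity <- obesity_new

  dropped <- sum(!ok)
  if (dropped > 0)
    message("dropped ", dropped, " of ", n_in, " row(s) failing validation")
  df <- df[ok, , drop = FALSE]
  rownames(df) <- NULL

  structure(df,
            annotation = annotation,
            log = list(n_input = n_in, n_dropped = dropped,
                       obesity_conflicts = conflicts),
            class = c("grs_cohort", "data.frame"))
}

#' @exportS3Method base::print
print.grs_cohort <- function(x, ...) {
  ann <- attr(x, "annotation")
  snps <- intersect(geno_col(ann$snp_id), names(x))
  cat("<grs_cohort> ", nrow(x), " subjects, ", length(snps),
      " genotyped SNP(s)\n", sep = "")
  cat("  obese: ", sum(x$obesity), " (",
      round(100 * mean(x$obesity), 1), "%); prevalent T2D: ",
      sum(x$t2d_prevalent), " (", round(100 * mean(x$t2d_prevalent), 1),
      "%)\n", sep = "")
  invisible(x)
}

#' Write a cohort in the package's CSV dialect
#'
#' @param cohort a `grs_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

# Genotype calls of one SNP from the cohort, erroring if absent.
cohort_calls <- function(cohort, snp_id) {
  col <- geno_col(snp_id)
  if (!col %in% names(cohort))
    stop("cohort has no genotype column for ", snp_id)
  cohort[[col]]
}

snp_annotation_row <- function(annotation, snp_id) {
  i <- match(snp_id, annotation$snp_id)
  if (is.na(i)) stop("SNP ", snp_id, " not present in annotation")
  annotation[i, , drop = FALSE]
}
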