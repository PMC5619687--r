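# Readers and writers for the pipeline's tabular formats. Missing values
# are serialized as "NA" throughout.

#' Write / read METAL-style summary statistics
#'
#' Columns: `SNP`, `CHR`, `POS`, `A1` (effect allele), `A2`, `FREQ1`,
#' `BETA`, `SE`, `P`, `N_CASES`, `N_CONTROLS`. The reader also accepts
#' externally pre-computed tables with the same column semantics.
#'
#' @param summary Summary-statistics data.frame.
#' @param path File path.
#' @return `write_summary_stats()`: the path, invisibly;
#'   `read_summary_stats()`: the data.frame.
#' @export
write_summary_stats <- function(summary, path) {
  need <- c("SNP", "CHR", "POS", "A1", "A2", "FREQ1", "BETA", "SE", "P",
            "N_CASES", "N_CONTROLS")
  stopifnot(all(need %in% names(summary)))
  write.table(summary[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                  colClasses = c(SNP = "character", A1 = "character",
                                 A2 = "character", CHR = "character"))
  need <- c("SNP", "CHR", "POS", "A1", "A2", "FREQ1", "BETA", "SE", "P")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("summary table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x
}

#' Write a gene association table
#'
#' Columns: `gene`, `study`, `zscore`, `pvalue`, `n_model_snps`,
#' `n_snps_used` (plus `sigma_g` when present).
#'
#' @param genes Gene association data.frame.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_gene_assoc <- function(genes, path) {
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort or panel to TSV files
#'
#' Emits `dosage.tsv` (rows = samples, columns = variant ids),
#' `variants.tsv` (`id`, `chrom`, `pos`, `ref`, `alt`, `freq`), and for
#' cohorts `phenotype.tsv` (phenotype + covariates). For a panel an
#' `expression.tsv` (samples x genes) is written instead.
#'
#' @param x A `sim_cohort` or `sim_panel`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulated_tsv <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(data.frame(sample = rownames(x$dosage), x$dosage,
                         check.names = FALSE),
              file.path(dir, "dosage.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(x$variants[, c("id", "chrom", "pos", "ref", "alt", "freq")],
              file.path(dir, "variants.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (inherits(x, "sim_cohort")) {
    write.table(data.frame(sample = rownames(x$dosage),
                           phenotype = x$phenotype, x$covariates),
                file.path(dir, "phenotype.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    write.table(data.frame(sample = rownames(x$expression), x$expression,
                           check.names = FALSE),
                file.path(dir, "expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Write the simulation ground truth
#'
#' One row per gene: `gene`, `gamma`, `h2_cis` — the generative effects a
#' parameter-recovery analysis should reproduce.
#'
#' @param architectures List of [gene_architecture()] objects.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_truth_tsv <- function(architectures, path) {
  tr <- data.frame(
    gene = vapply(architectures, `[[`, "", "gene_id"),
    gamma = vapply(architectures, `[[`, 0, "gamma"),
    h2_cis = vapply(architectures, `[[`, 0, "h2_cis"))
  write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a pipeline file against its expected schema
#'
#' Checks header columns, column types, allele characters and coordinate
#' positivity for the pipeline's tabular formats and returns a
#' machine-readable report rather than failing, so callers can decide how
#' to proceed.
#'
#' @param path File to check.
#' @param format One of `"summary"`, `"weights"`, `"covariance"`,
#'   `"gene_assoc"`, `"locus_catalog"`, `"variants"`.
#' @return List with `ok` (logical), `errors` and `warnings` (character
#'   vectors).
#' @export
validate_formats <- function(path, format) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schemas <- list(
    summary = c("SNP", "CHR", "POS", "A1", "A2", "FREQ1", "BETA", "SE",
                "P"),
    weights = c("gene", "rsid", "ref_allele", "eff_allele", "weight",
                "cv_r2"),
    covariance = c("GENE", "RSID1", "RSID2", "VALUE"),
    gene_assoc = c("gene", "study", "zscore", "pvalue"),
    locus_catalog = c("locus_id", "chrom", "pos"),
    variants = c("id", "chrom", "pos", "ref", "alt", "freq"))
  if (!format %in% names(schemas))
    stop("unknown format: ", format, call. = FALSE)
  errors <- character(); warnings <- character()
  x <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(schemas[[format]], names(x))
  if (length(miss))
    errors <- c(errors, paste0("missing columns: ",
                               paste(miss, collapse = ", ")))
  if (!length(miss) && nrow(x)) {
    numcols <- intersect(c("POS", "FREQ1", "BETA", "SE", "P", "weight",
                           "cv_r2", "VALUE", "pos", "freq", "zscore",
                           "pvalue"), names(x))
    for (cc in numcols) {
      v <- suppressWarnings(as.numeric(x[[cc]]))
      newna <- sum(is.na(v)) - sum(is.na(x[[cc]]))
      if (newna > 0)
        errors <- c(errors, paste0("non-numeric values in ", cc))
      else if (anyNA(v))
        warnings <- c(warnings,
                      paste0("NA values in ", cc, "; rows kept as missing"))
    }
    for (cc in intersect(c("POS", "pos"), names(x)))
      if (any(x[[cc]] <= 0, na.rm = TRUE))
        errors <- c(errors, paste0("non-positive coordinates in ", cc))
    for (cc in intersect(c("A1", "A2", "ref", "alt", "ref_allele",
                           "eff_allele"), names(x)))
      if (any(!grepl("^[ACGT]+$", x[[cc]])))
        errors <- c(errors, paste0("invalid allele characters in ", cc))
    idcol <- intersect(c("SNP", "id"), names(x))
    if (length(idcol) && anyDuplicated(x[[idcol[1]]]))
      errors <- c(errors,
                  paste0("duplicated variant id: ",
                         x[[idcol[1]]][duplicated(x[[idcol[1]]])][1]))
  }
  list(ok = length(errors) == 0, errors = errors, warnings = warnings)
}
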