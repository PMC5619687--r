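# Bundled association tables from a published multi-ancestry breast cancer
# case-control analysis (cohorts of African, European and Asian ancestry).
# They carry the per-study gene Z-scores, per-study SNP odds ratios with
# confidence intervals, and cohort case/control counts, and serve as known
# totals for validating the meta-analysis arithmetic.

#' Load the bundled multi-ancestry breast cancer study tables
#'
#' Returns the per-study gene-level Z-scores (overall and estrogen-receptor
#' negative scans, including the published combined "Total" rows and FDR
#' column), the per-study SNP odds ratios with 95% confidence intervals for
#' the TP53INP2 predictor SNPs (discovery and external replication phases),
#' and the cohort case/control counts.
#'
#' @return A list with components:
#'   \describe{
#'     \item{genes}{data.frame `phenotype`, `gene`, `cytoband`,
#'       `snps_in_predictor`, `study`, `zscore`, `pvalue`, `fdr`; the
#'       `study == "Total"` rows are the published combined statistics.}
#'     \item{snps}{data.frame of per-study and meta SNP odds ratios with
#'       CI bounds for both phenotypes.}
#'     \item{replication}{data.frame of discovery-phase (BPC3 removed) and
#'       external replication odds ratios for the same SNPs.}
#'     \item{cohorts}{data.frame `study`, `population`, `n_cases_overall`,
#'       `n_cases_er_negative`, `n_controls`.}
#'   }
#' @export
#' @examples
#' fx <- load_study_fixtures()
#' subset(fx$genes, gene == "TP53INP2" & phenotype == "er_negative")
load_study_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "twasmeta",
                                  mustWork = TRUE)
  rd <- function(f) read.delim(path(f), stringsAsFactors = FALSE)
  list(genes = rd("gene_associations.tsv"),
       snps = rd("snp_associations.tsv"),
       replication = rd("snp_replication.tsv"),
       cohorts = rd("cohort_counts.tsv"))
}

#' Effective sample sizes of the bundled cohorts
#'
#' Convenience wrapper: case-control effective sample size
#' `4 / (1/n_cases + 1/n_controls)` for each bundled cohort, for one
#' phenotype.
#'
#' @param phenotype `"overall"` or `"er_negative"`.
#' @param cohorts Cohort count table; defaults to the bundled one.
#' @return Named numeric vector of effective sizes (studies without the
#'   phenotype are dropped).
#' @export
fixture_effective_n <- function(phenotype = c("er_negative", "overall"),
                                cohorts = load_study_fixtures()$cohorts) {
  phenotype <- match.arg(phenotype)
  nc <- if (phenotype == "overall") cohorts$n_cases_overall
        else cohorts$n_cases_er_negative
  keep <- !is.na(nc)
  setNames(effective_n(nc[keep], cohorts$n_controls[keep]),
           cohorts$study[keep])
}
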