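# Combination of per-study results across ancestry groups: sample-size
# weighted gene-level Z meta-analysis, fixed-effect inverse-variance
# SNP-level meta-analysis with CI reconstruction, and Cochran's Q.

#' Case-control effective sample size
#'
#' `4 / (1/n_cases + 1/n_controls)` — the balanced-design size carrying the
#' same information as the unbalanced study; used as the weight in the
#' gene-level Z meta-analysis.
#'
#' @param n_cases,n_controls Counts, both at least 1 (vectorized).
#' @return Numeric effective sample size.
#' @export
effective_n <- function(n_cases, n_controls) {
  stopifnot(all(n_cases >= 1), all(n_controls >= 1))
  4 / (1 / n_cases + 1 / n_controls)
}

#' Sample-size-weighted gene-level Z meta-analysis
#'
#' Combines per-study gene Z-scores with square-root effective-sample-size
#' weights:
#' \deqn{Z_{meta} = \frac{\sum_k \sqrt{N_k} Z_k}{\sqrt{\sum_k N_k}}}
#' Studies with a missing Z for a gene are omitted from both sums, so a
#' gene absent from one cohort is combined over the remaining cohorts.
#'
#' @param gene_results data.frame with columns `gene`, `study`, `zscore`
#'   (stacked per-study tables from [run_study_genescan()]).
#' @param neff Named numeric vector of per-study effective sample sizes
#'   (names matching `study`).
#' @return data.frame, one row per gene: `gene`, `zscore`, `pvalue`,
#'   `n_studies`; attribute `"contributions"` lists per-gene `(study, Z,
#'   Neff)`.
#' @export
meta_z_genes <- function(gene_results, neff) {
  stopifnot(all(c("gene", "study", "zscore") %in% names(gene_results)))
  miss <- setdiff(unique(gene_results$study), names(neff))
  if (length(miss))
    stop("no effective sample size for study: ",
         paste(miss, collapse = ", "), call. = FALSE)
  contribs <- list()
  rows <- lapply(split(gene_results, gene_results$gene), function(gr) {
    gene <- gr$gene[1]
    gr <- gr[is.finite(gr$zscore), , drop = FALSE]
    if (nrow(gr) == 0)
      return(data.frame(gene = gene, zscore = NA_real_,
                        pvalue = NA_real_, n_studies = 0L,
                        stringsAsFactors = FALSE))
    n <- neff[gr$study]
    z <- sum(sqrt(n) * gr$zscore) / sqrt(sum(n))
    contribs[[gr$gene[1]]] <<- data.frame(study = gr$study,
                                          zscore = gr$zscore, neff = n,
                                          row.names = NULL)
    data.frame(gene = gr$gene[1], zscore = z,
               pvalue = 2 * pnorm(-abs(z)), n_studies = nrow(gr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contributions") <- contribs
  out
}

#' Log-scale standard error from an odds ratio confidence interval
#'
#' Reconstructs the standard error of the log odds ratio from printed 95%
#' bounds: `se = (ln(ci_high) - ln(ci_low)) / (2 * 1.96)`. The 1.96
#' quantile (not a higher-precision value) matches how printed intervals
#' are formed.
#'
#' @param or_point Odds ratio point estimate (unused in the arithmetic but
#'   kept for record checking; may be `NULL`).
#' @param ci_low,ci_high Positive CI bounds, `ci_low <= ci_high`.
#' @return Standard error on the log odds scale.
#' @export
se_from_ci <- function(or_point = NULL, ci_low, ci_high) {
  if (any(ci_low <= 0) || any(ci_high <= 0))
    stop("confidence bounds must be positive", call. = FALSE)
  if (any(ci_high < ci_low))
    stop("ci_high must be >= ci_low", call. = FALSE)
  (log(ci_high) - log(ci_low)) / (2 * 1.96)
}

#' Fixed-effect inverse-variance SNP meta-analysis
#'
#' Combines per-study log odds ratios with weights `1/se^2`; the combined
#' estimate is `sum(w*beta)/sum(w)` with standard error `1/sqrt(sum(w))`.
#' The odds ratio and 95% CI are recovered by exponentiation with the 1.96
#' quantile. Cochran's Q heterogeneity is attached when at least two
#' studies contribute.
#'
#' @param beta Numeric vector of per-study log odds ratios.
#' @param se Matching positive standard errors.
#' @return One-row data.frame: `beta`, `se`, `or`, `ci_low`, `ci_high`,
#'   `pvalue`, `q`, `p_het`, `n_studies` (heterogeneity fields `NA` for a
#'   single study).
#' @export
ivw_meta_snp <- function(beta, se) {
  if (!length(beta)) stop("no studies to combine", call. = FALSE)
  stopifnot(length(beta) == length(se), all(se > 0))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  het <- cochran_q(beta, se)
  data.frame(beta = b, se = s, or = exp(b),
             ci_low = exp(b - 1.96 * s), ci_high = exp(b + 1.96 * s),
             pvalue = 2 * pnorm(-abs(b / s)),
             q = het$q, p_het = het$p_het, n_studies = length(beta))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_k w_k (beta_k - beta_meta)^2` with inverse-variance weights,
#' referred to a chi-square with `K - 1` degrees of freedom.
#'
#' @param beta Per-study log odds ratios.
#' @param se Matching positive standard errors.
#' @return List `q`, `p_het` (both `NA` when fewer than two studies).
#' @export
cochran_q <- function(beta, se) {
  stopifnot(length(beta) == length(se))
  if (length(beta) < 2) return(list(q = NA_real_, p_het = NA_real_))
  stopifnot(all(se > 0))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - b)^2)
  list(q = q, p_het = pchisq(q, df = length(beta) - 1, lower.tail = FALSE))
}

#' Meta-analyze a per-study SNP odds-ratio table
#'
#' Convenience wrapper over [se_from_ci()] and [ivw_meta_snp()] for tables
#' holding per-study `or`, `ci_low`, `ci_high` rows per SNP (such as the
#' bundled study fixtures).
#'
#' @param snp_table data.frame with columns `snp`, `or`, `ci_low`,
#'   `ci_high` (one row per contributing study; any `study == "meta"` rows
#'   must be excluded by the caller).
#' @return data.frame, one row per SNP, as from [ivw_meta_snp()] with a
#'   leading `snp` column.
#' @export
meta_snp_table <- function(snp_table) {
  stopifnot(all(c("snp", "or", "ci_low", "ci_high") %in% names(snp_table)))
  rows <- lapply(split(snp_table, snp_table$snp), function(g) {
    se <- se_from_ci(g$or, g$ci_low, g$ci_high)
    cbind(snp = g$snp[1], ivw_meta_snp(log(g$or), se))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
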