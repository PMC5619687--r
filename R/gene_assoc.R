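# Summary-statistic gene-level association: harmonize GWAS summaries to
# model alleles, reduce models for SNPs missing or monomorphic in a study,
# and compute the gene Z-score from weights, per-SNP Wald Z-scores, and the
# reference LD covariance.

#' Harmonize a summary-statistics table to a gene model's alleles
#'
#' For each model SNP found in the summary table: if the summary effect
#' allele matches the model effect allele the record is kept as is; if the
#' allele pair is swapped the log odds ratio is negated and the frequency
#' replaced by `1 - f`; strand-ambiguous (A/T, C/G) SNPs are kept by
#' default with a flag, or dropped via `drop_ambiguous`. Allele pairs that
#' neither match nor swap are dropped with a logged reason.
#'
#' @param summary data.frame with METAL-style columns `SNP`, `A1`, `A2`,
#'   `FREQ1`, `BETA`, `SE` (as emitted by [run_study_gwas()]).
#' @param model A `prediction_model`.
#' @param drop_ambiguous Drop strand-ambiguous SNPs instead of flagging.
#' @return data.frame with one row per usable model SNP: `snp`, `beta`,
#'   `se`, `freq`, `zscore`, `ambiguous`; attribute `"dropped"` is a
#'   data.frame of dropped SNPs and reasons (`absent`, `allele_mismatch`,
#'   `ambiguous`, `missing_estimate`).
#' @export
harmonize <- function(summary, model, drop_ambiguous = FALSE) {
  w <- model$weights
  rows <- vector("list", nrow(w))
  dropped <- list()
  note <- function(snp, why) dropped[[length(dropped) + 1L]] <<-
    data.frame(snp = snp, reason = why, stringsAsFactors = FALSE)
  amb_pair <- function(a, b) (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  for (i in seq_len(nrow(w))) {
    snp <- w$snp[i]
    j <- match(snp, summary$SNP)
    if (is.na(j)) { note(snp, "absent"); next }
    a1 <- toupper(summary$A1[j]); a2 <- toupper(summary$A2[j])
    eff <- toupper(w$eff_allele[i]); ref <- toupper(w$ref_allele[i])
    if (is.na(summary$BETA[j]) || is.na(summary$SE[j])) {
      note(snp, "missing_estimate"); next
    }
    if (a1 == eff && a2 == ref) {
      beta <- summary$BETA[j]; freq <- summary$FREQ1[j]
    } else if (a1 == ref && a2 == eff) {
      beta <- -summary$BETA[j]; freq <- 1 - summary$FREQ1[j]
    } else {
      note(snp, "allele_mismatch"); next
    }
    amb <- amb_pair(a1, a2)
    if (amb && drop_ambiguous) { note(snp, "ambiguous"); next }
    if (amb)
      warning("strand-ambiguous alleles kept for ", snp, call. = FALSE)
    rows[[i]] <- data.frame(snp = snp, beta = beta, se = summary$SE[j],
                            freq = freq, zscore = beta / summary$SE[j],
                            ambiguous = amb, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(snp = character(), beta = numeric(), se = numeric(),
                      freq = numeric(), zscore = numeric(),
                      ambiguous = logical(), stringsAsFactors = FALSE)
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
    else data.frame(snp = character(), reason = character())
  out
}

#' Reduce a gene model to the SNPs available in a study
#'
#' Drops model SNPs that are absent from the study (not genotyped,
#' monomorphic, filtered by MAF, or lost in harmonization) and restricts
#' the reference covariance to the surviving rows and columns, mirroring
#' the published handling of a predictor SNP monomorphic in one cohort.
#'
#' @param model A `prediction_model`.
#' @param covariance The matching `snp_covariance`.
#' @param available Character vector of variant ids usable in the study.
#' @return List with `model` (reduced), `covariance` (reduced),
#'   `n_model_snps`, `n_snps_used`.
#' @export
reduce_model <- function(model, covariance, available) {
  stopifnot(identical(model$weights$snp, covariance$snps))
  keep <- model$weights$snp %in% available
  red <- model
  red$weights <- model$weights[keep, , drop = FALSE]
  cv <- covariance
  cv$snps <- covariance$snps[keep]
  cv$sigma <- covariance$sigma[keep, keep, drop = FALSE]
  list(model = red, covariance = cv,
       n_model_snps = nrow(model$weights),
       n_snps_used = sum(keep))
}

#' Summary-based gene association Z-score
#'
#' The gene-level statistic combines the model weights `w`, each SNP's
#' Wald Z-score `beta/se` from the study, and the reference LD covariance
#' `Gamma`:
#' \deqn{Z_g = \sum_l w_l \frac{\sigma_l}{\sigma_g} \frac{\beta_l}{se_l}}
#' with \eqn{\sigma_l = \sqrt{\Gamma_{ll}}} and
#' \eqn{\sigma_g = \sqrt{w^\top \Gamma w}} the standard deviation of the
#' predicted expression in the reference panel. A positive Z means higher
#' predicted expression associates with higher risk. With a degenerate
#' covariance (`w'Gamma w <= 0`) or no usable SNPs a missing-value record
#' is returned.
#'
#' @param model Reduced `prediction_model`.
#' @param covariance Reduced `snp_covariance` in the same SNP order.
#' @param harmonized Aligned per-SNP records from [harmonize()] (rows for
#'   the reduced model's SNPs).
#' @param study Study label carried into the output.
#' @param n_model_snps Count of SNPs in the stored (unreduced) model.
#' @return One-row data.frame: `gene`, `study`, `zscore`, `pvalue`,
#'   `sigma_g`, `n_model_snps`, `n_snps_used`.
#' @export
gene_zscore <- function(model, covariance, harmonized, study = NA_character_,
                        n_model_snps = nrow(model$weights)) {
  miss <- function(used = 0L) data.frame(
    gene = model$gene_id, study = study, zscore = NA_real_,
    pvalue = NA_real_, sigma_g = NA_real_,
    n_model_snps = n_model_snps, n_snps_used = used,
    stringsAsFactors = FALSE)
  if (nrow(model$weights) == 0) return(miss())
  idx <- match(model$weights$snp, harmonized$snp)
  if (anyNA(idx)) return(miss())
  w <- model$weights$weight
  G <- covariance$sigma
  sig2 <- as.numeric(t(w) %*% G %*% w)
  if (!is.finite(sig2) || sig2 <= 0) return(miss(length(w)))
  sigma_g <- sqrt(sig2)
  z <- sum(w * sqrt(diag(G)) * harmonized$zscore[idx]) / sigma_g
  data.frame(gene = model$gene_id, study = study, zscore = z,
             pvalue = 2 * pnorm(-abs(z)), sigma_g = sigma_g,
             n_model_snps = n_model_snps, n_snps_used = length(w),
             stringsAsFactors = FALSE)
}

#' Gene-level association scan of one study from summary statistics
#'
#' For every testable gene model: harmonize the study's summary statistics
#' to the model alleles, reduce the model to the usable SNPs (present,
#' polymorphic at the MAF threshold, allele-consistent), and compute the
#' summary-based gene Z-score.
#'
#' @param summary METAL-style summary table for the study.
#' @param models Named list of `prediction_model` objects.
#' @param covariances Named list of matching `snp_covariance` objects.
#' @param study Study label.
#' @param maf_threshold Frequency filter applied to the study's summary
#'   rows; SNPs at or below it (or monomorphic) are treated as unavailable.
#' @param drop_ambiguous Passed to [harmonize()].
#' @return data.frame sorted by gene id, one row per testable gene:
#'   `gene`, `study`, `zscore`, `pvalue`, `sigma_g`, `n_model_snps`,
#'   `n_snps_used`. Attribute `"reductions"` logs per-gene dropped SNPs.
#' @export
run_study_genescan <- function(summary, models, covariances,
                               study = "study", maf_threshold = 0.05,
                               drop_ambiguous = FALSE) {
  genes <- sort(names(models))
  logs <- list()
  rows <- lapply(genes, function(g) {
    m <- models[[g]]
    if (!isTRUE(m$testable) || nrow(m$weights) == 0) return(NULL)
    h <- harmonize(summary, m, drop_ambiguous = drop_ambiguous)
    poly <- h$snp[pmin(h$freq, 1 - h$freq) > maf_threshold]
    red <- reduce_model(m, covariances[[g]], poly)
    logs[[g]] <<- attr(h, "dropped")
    gene_zscore(red$model, red$covariance, h, study = study,
                n_model_snps = red$n_model_snps)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), study = character(),
                      zscore = numeric(), pvalue = numeric(),
                      sigma_g = numeric(), n_model_snps = integer(),
                      n_snps_used = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "reductions") <- logs
  out
}
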