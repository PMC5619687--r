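# Per-study SNP-level association: MAF filtering, genotype PCA covariates,
# additive logistic regression, METAL-style summary statistics.

#' Filter variants on minor allele frequency
#'
#' Retains variants whose minor allele frequency `min(f, 1 - f)` is
#' strictly greater than `threshold`.
#'
#' @param variants data.frame with columns `id` and `freq` (effect-allele
#'   frequency in `[0, 1]`), or a named numeric frequency vector.
#' @param threshold MAF cutoff; default 0.05.
#' @return Character vector of retained variant ids.
#' @export
maf_filter <- function(variants, threshold = 0.05) {
  if (is.numeric(variants)) {
    f <- variants
    id <- names(variants)
    if (is.null(id)) id <- as.character(seq_along(f))
  } else {
    f <- variants$freq
    id <- variants$id
  }
  if (any(f < 0 | f > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  # tiny epsilon so 1 - 0.95 compares equal to a 0.05 threshold
  id[!is.na(f) & pmin(f, 1 - f) > threshold + 1e-12]
}

#' Principal components of a standardized dosage matrix
#'
#' Columns are centered and scaled to unit variance (constant columns are
#' dropped before the decomposition) and the leading `k` principal axes
#' are returned, as used for population-stratification adjustment.
#'
#' @param dosage Numeric matrix, samples x variants.
#' @param k Number of leading components.
#' @return List of class `pc_result` with `scores` (samples x k, column
#'   orthogonal) and `eigenvalues` (non-increasing variances).
#' @export
compute_pcs <- function(dosage, k = 4L) {
  v <- apply(dosage, 2, var)
  keep <- which(v > 0)
  if (!length(keep))
    stop("no variable sites: every dosage column is constant", call. = FALSE)
  x <- scale(dosage[, keep, drop = FALSE])
  pr <- prcomp(x, center = FALSE, scale. = FALSE)
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-8)
  if (k > rank)
    stop("k = ", k, " exceeds the available rank; at most ", rank,
         " components are attainable", call. = FALSE)
  structure(list(scores = pr$x[, seq_len(k), drop = FALSE],
                 eigenvalues = pr$sdev[seq_len(k)]^2),
            class = "pc_result")
}

#' Additive-model logistic regression for one SNP
#'
#' Maximum-likelihood Wald estimate of the per-allele log odds ratio by
#' iteratively reweighted least squares (convergence tolerance 1e-8, at
#' most 50 iterations). Non-convergence or separation yields a
#' missing-value record rather than an error, so a genome scan can
#' continue past pathological sites.
#'
#' @param dosage Numeric dosage vector (0-2 scale).
#' @param phenotype Binary 0/1 vector, aligned with `dosage`.
#' @param covariates Optional numeric matrix/data.frame of covariates.
#' @return Named list `beta`, `se`, `p`, `converged`.
#' @export
fit_snp_logistic <- function(dosage, phenotype, covariates = NULL) {
  stopifnot(length(dosage) == length(phenotype),
            all(phenotype %in% c(0, 1)))
  if (var(dosage) == 0)
    stop("dosage is constant; filter monomorphic sites first", call. = FALSE)
  x <- cbind(`(Intercept)` = 1, dosage = dosage)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(dosage))
    x <- cbind(x, covariates)
  }
  fit <- suppressWarnings(
    glm.fit(x, phenotype, family = binomial(),
            control = glm.control(epsilon = 1e-8, maxit = 50L)))
  beta <- unname(fit$coefficients["dosage"])
  # covariance of coefficients from the final IRLS weighted least squares
  ok <- fit$converged && !fit$boundary && is.finite(beta) && abs(beta) < 15
  se <- NA_real_
  if (ok) {
    p1 <- fit$rank
    Rmat <- fit$qr$qr[seq_len(p1), seq_len(p1), drop = FALSE]
    Rmat[lower.tri(Rmat)] <- 0
    covmat <- tryCatch(chol2inv(Rmat), error = function(e) NULL)
    j <- match("dosage", colnames(x)[fit$qr$pivot[seq_len(p1)]])
    if (!is.null(covmat) && !is.na(j) && covmat[j, j] > 0)
      se <- sqrt(covmat[j, j])
  }
  if (!ok || !is.finite(se) || se > 100)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                converged = FALSE))
  list(beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
       converged = TRUE)
}

#' Run the SNP-level GWAS for one cohort
#'
#' Applies the MAF filter to realized cohort allele frequencies, computes
#' genotype principal components, fits every retained SNP by additive
#' logistic regression adjusting for the PCs and the cohort covariates,
#' and emits a METAL-style summary table sorted by (chromosome, position).
#'
#' @param cohort A `sim_cohort` (or a list with `dosage`, `variants`,
#'   `phenotype`, `covariates`, `spec`).
#' @param k_pcs Number of principal components to adjust for (default 4).
#' @param maf_threshold MAF cutoff; default 0.05.
#' @param covariate_cols Names of `cohort$covariates` columns to adjust
#'   for in addition to the PCs.
#' @return data.frame with columns `SNP`, `CHR`, `POS`, `A1` (effect
#'   allele), `A2`, `FREQ1`, `BETA`, `SE`, `P`, `N_CASES`, `N_CONTROLS`.
#'   SNPs with failed fits carry `NA` in `BETA`/`SE`/`P`.
#' @export
run_study_gwas <- function(cohort, k_pcs = 4L, maf_threshold = 0.05,
                           covariate_cols = "age") {
  freq <- colMeans(cohort$dosage) / 2
  keep <- maf_filter(setNames(freq, colnames(cohort$dosage)),
                     maf_threshold)
  if (!length(keep))
    stop("no variants pass the MAF filter", call. = FALSE)
  dos <- cohort$dosage[, keep, drop = FALSE]
  covm <- NULL
  if (k_pcs > 0)
    covm <- compute_pcs(dos, k_pcs)$scores
  if (length(covariate_cols)) {
    extra <- as.matrix(cohort$covariates[, covariate_cols, drop = FALSE])
    covm <- if (is.null(covm)) extra else cbind(covm, extra)
  }
  fits <- lapply(keep, function(s)
    fit_snp_logistic(dos[, s], cohort$phenotype, covm))
  vt <- cohort$variants[match(keep, cohort$variants$id), ]
  out <- data.frame(
    SNP = keep, CHR = vt$chrom, POS = vt$pos, A1 = vt$alt, A2 = vt$ref,
    FREQ1 = unname(freq[keep]),
    BETA = vapply(fits, `[[`, 0, "beta"),
    SE = vapply(fits, `[[`, 0, "se"),
    P = vapply(fits, `[[`, 0, "p"),
    N_CASES = sum(cohort$phenotype == 1),
    N_CONTROLS = sum(cohort$phenotype == 0),
    stringsAsFactors = FALSE)
  out <- out[order(out$CHR, out$POS, out$SNP), ]
  rownames(out) <- NULL
  out
}
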