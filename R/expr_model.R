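# Per-gene elastic-net expression prediction weights trained on the
# reference panel, and the per-gene reference LD covariance consumed by the
# summary-statistic gene association.

#' Train an elastic-net cis-eQTL prediction model for one gene
#'
#' Fits expression on cis dosages (SNPs within `cis_window` of the
#' transcription start site that pass the MAF filter) with the elastic net,
#' choosing the penalty by k-fold cross-validation minimizing mean squared
#' error. The mixing parameter defaults to 0.5, halfway between ridge
#' regression and the lasso, which makes the weights robust to missing or
#' low-quality genotypes in downstream studies. Genes whose cross-validated
#' R-squared does not exceed `weak_r2` are flagged untestable and skipped by
#' the gene scan.
#'
#' @param panel A `sim_panel` (dosage + expression + variant table).
#' @param gene_id Gene to train.
#' @param cis_window Base pairs around the TSS searched for predictors
#'   (default 1 Mb).
#' @param mixing Elastic-net mixing parameter in `[0, 1]` (default 0.5).
#' @param folds Cross-validation folds (default 10).
#' @param seed Seed for the fold assignment (deterministic fit).
#' @param maf_threshold MAF cutoff for candidate cis SNPs.
#' @param weak_r2 Cross-validated R-squared at or below which the model is
#'   flagged untestable (default 0.01).
#' @return Object of class `prediction_model`: list with `gene_id`,
#'   `weights` (data.frame `snp`, `ref_allele`, `eff_allele`, `weight`;
#'   nonzero weights only, per copy of the effect allele), `mixing`,
#'   `lambda`, `cv_r2` (clipped at 0), `testable`.
#' @export
train_elastic_net <- function(panel, gene_id, cis_window = 1e6,
                              mixing = 0.5, folds = 10L, seed = 1L,
                              maf_threshold = 0.05, weak_r2 = 0.01) {
  stopifnot(inherits(panel, "sim_panel"))
  arch <- NULL
  for (a in panel$architectures) if (a$gene_id == gene_id) arch <- a
  if (is.null(arch))
    stop("gene ", gene_id, " not present in panel", call. = FALSE)
  vt <- panel$variants
  freq <- colMeans(panel$dosage) / 2
  cis <- vt$id[vt$chrom == arch$chrom & abs(vt$pos - arch$tss) <= cis_window]
  cis <- intersect(cis, maf_filter(setNames(freq, vt$id), maf_threshold))
  empty <- function(r2) structure(
    list(gene_id = gene_id,
         weights = data.frame(snp = character(), ref_allele = character(),
                              eff_allele = character(), weight = numeric(),
                              stringsAsFactors = FALSE),
         mixing = mixing, lambda = NA_real_, cv_r2 = r2, testable = FALSE),
    class = "prediction_model")
  if (!length(cis)) return(empty(NA_real_))

  y <- panel$expression[, gene_id]
  x <- panel$dosage[, cis, drop = FALSE]
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = length(y)))
  if (length(cis) == 1L) {
    # glmnet needs >= 2 predictors; a single cis SNP reduces to simple
    # ordinary least squares with fold-held-out R-squared
    b <- cov(x[, 1], y) / var(x[, 1])
    press <- 0
    for (f in seq_len(folds)) {
      tr <- foldid != f
      bf <- cov(x[tr, 1], y[tr]) / var(x[tr, 1])
      af <- mean(y[tr]) - bf * mean(x[tr, 1])
      press <- press + sum((y[!tr] - af - bf * x[!tr, 1])^2)
    }
    cv_r2 <- max(0, 1 - press / length(y) / var(y))
    w <- data.frame(snp = cis, stringsAsFactors = FALSE)
    w$ref_allele <- vt$ref[match(cis, vt$id)]
    w$eff_allele <- vt$alt[match(cis, vt$id)]
    w$weight <- b
    mod <- structure(list(gene_id = gene_id, weights = w, mixing = mixing,
                          lambda = NA_real_, cv_r2 = cv_r2,
                          testable = cv_r2 > weak_r2),
                     class = "prediction_model")
    if (!mod$testable || b == 0) mod$weights <- mod$weights[0, ]
    if (nrow(mod$weights) == 0) mod$testable <- FALSE
    return(mod)
  }
  cvfit <- glmnet::cv.glmnet(x, y, alpha = mixing, foldid = foldid,
                             nlambda = 100L, standardize = TRUE)
  cv_r2 <- max(0, 1 - min(cvfit$cvm) / var(y))
  co <- as.matrix(coef(cvfit, s = "lambda.min"))[-1, 1]
  nz <- which(co != 0)
  w <- data.frame(snp = cis[nz],
                  ref_allele = vt$ref[match(cis[nz], vt$id)],
                  eff_allele = vt$alt[match(cis[nz], vt$id)],
                  weight = unname(co[nz]), stringsAsFactors = FALSE)
  structure(list(gene_id = gene_id, weights = w, mixing = mixing,
                 lambda = cvfit$lambda.min, cv_r2 = cv_r2,
                 testable = cv_r2 > weak_r2 && nrow(w) > 0),
            class = "prediction_model")
}

#' @export
print.prediction_model <- function(x, ...) {
  cat("Prediction model for", x$gene_id, "-", nrow(x$weights),
      "SNPs, cv R^2 =", signif(x$cv_r2, 3),
      if (!x$testable) "(untestable)" else "", "\n")
  invisible(x)
}

#' Reference LD covariance of a gene's model SNPs
#'
#' Sample covariance (denominator n-1) of the model SNPs' dosages in the
#' reference panel, in model SNP order. This is the LD information the
#' summary-based gene statistic needs in place of individual genotypes.
#'
#' @param dosage Reference dosage matrix (samples x variants, named
#'   columns), or a `sim_panel`.
#' @param model A `prediction_model`.
#' @return Object of class `snp_covariance`: list with `gene_id`, `snps`,
#'   and `sigma` (symmetric positive semi-definite matrix).
#' @export
build_covariance <- function(dosage, model) {
  if (inherits(dosage, "sim_panel")) dosage <- dosage$dosage
  stopifnot(inherits(model, "prediction_model"))
  miss <- setdiff(model$weights$snp, colnames(dosage))
  if (length(miss))
    stop("model SNP absent from panel: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- dosage[, model$weights$snp, drop = FALSE]
  structure(list(gene_id = model$gene_id, snps = model$weights$snp,
                 sigma = cov(x)),
            class = "snp_covariance")
}

#' Write a model database (weights + covariances) as TSV
#'
#' Weight table columns: `gene`, `rsid`, `ref_allele`, `eff_allele`,
#' `weight`, `cv_r2`. Covariance file in long format: `GENE RSID1 RSID2
#' VALUE` with `(gene, rsid1, rsid2)` sorted, upper triangle including the
#' diagonal. The round trip through [read_model_db()] is lossless.
#'
#' @param models List of `prediction_model` objects.
#' @param covariances List of `snp_covariance` objects (same genes).
#' @param weights_path,cov_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_model_db <- function(models, covariances, weights_path, cov_path) {
  wt <- do.call(rbind, lapply(models, function(m) {
    if (nrow(m$weights) == 0) return(NULL)
    data.frame(gene = m$gene_id, rsid = m$weights$snp,
               ref_allele = m$weights$ref_allele,
               eff_allele = m$weights$eff_allele,
               weight = m$weights$weight, cv_r2 = m$cv_r2,
               stringsAsFactors = FALSE)
  }))
  if (is.null(wt))
    wt <- data.frame(gene = character(), rsid = character(),
                     ref_allele = character(), eff_allele = character(),
                     weight = numeric(), cv_r2 = numeric())
  wt <- wt[order(wt$gene, wt$rsid), ]
  write.table(wt, weights_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cv <- do.call(rbind, lapply(covariances, function(cm) {
    s <- cm$snps
    if (!length(s)) return(NULL)
    idx <- which(upper.tri(cm$sigma, diag = TRUE), arr.ind = TRUE)
    data.frame(GENE = cm$gene_id, RSID1 = s[idx[, 1]], RSID2 = s[idx[, 2]],
               VALUE = cm$sigma[idx], stringsAsFactors = FALSE)
  }))
  if (is.null(cv))
    cv <- data.frame(GENE = character(), RSID1 = character(),
                     RSID2 = character(), VALUE = numeric())
  cv <- cv[order(cv$GENE, cv$RSID1, cv$RSID2), ]
  write.table(cv, cov_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(weights_path, cov_path))
}

#' Read a model database written by [write_model_db()]
#'
#' @param weights_path,cov_path Paths to the weight and covariance TSVs.
#' @return List with `models` (named list of `prediction_model`) and
#'   `covariances` (named list of `snp_covariance`).
#' @export
read_model_db <- function(weights_path, cov_path) {
  wt <- read.delim(weights_path, stringsAsFactors = FALSE,
                   comment.char = "#")
  need <- c("gene", "rsid", "ref_allele", "eff_allele", "weight", "cv_r2")
  if (!all(need %in% names(wt)))
    stop("malformed weight table: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(wt$weight))
  if (length(bad))
    stop("malformed weight value at line ", bad[1] + 1L, call. = FALSE)
  cv <- read.delim(cov_path, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (!all(c("GENE", "RSID1", "RSID2", "VALUE") %in% names(cv)))
    stop("malformed covariance file: expected GENE RSID1 RSID2 VALUE",
         call. = FALSE)
  badv <- which(!is.finite(cv$VALUE))
  if (length(badv))
    stop("malformed covariance value at line ", badv[1] + 1L, call. = FALSE)
  models <- lapply(split(wt, wt$gene), function(g) {
    g <- g[order(g$rsid), ]
    structure(list(gene_id = g$gene[1],
                   weights = data.frame(snp = g$rsid,
                                        ref_allele = g$ref_allele,
                                        eff_allele = g$eff_allele,
                                        weight = g$weight,
                                        stringsAsFactors = FALSE),
                   mixing = NA_real_, lambda = NA_real_,
                   cv_r2 = g$cv_r2[1], testable = TRUE),
              class = "prediction_model")
  })
  covariances <- lapply(split(cv, cv$GENE), function(g) {
    s <- sort(unique(c(g$RSID1, g$RSID2)))
    m <- matrix(NA_real_, length(s), length(s), dimnames = list(s, s))
    m[cbind(g$RSID1, g$RSID2)] <- g$VALUE
    m[cbind(g$RSID2, g$RSID1)] <- g$VALUE
    structure(list(gene_id = g$GENE[1], snps = s, sigma = m),
              class = "snp_covariance")
  })
  # align covariance SNP order with the model's
  for (g in names(models)) {
    if (!g %in% names(covariances)) next
    s <- models[[g]]$weights$snp
    if (all(s %in% covariances[[g]]$snps)) {
      covariances[[g]]$sigma <-
        covariances[[g]]$sigma[s, s, drop = FALSE]
      covariances[[g]]$snps <- s
    }
  }
  list(models = models, covariances = covariances)
}
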