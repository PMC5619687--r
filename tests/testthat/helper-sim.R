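# Shared builders for simulated fixtures. Everything is generated in code
# under fixed seeds; no binary fixtures.

# A set of gene architectures on one chromosome: `n_causal` genes carry a
# single causal eQTL with heritability `h2` and risk effect taken from
# `gammas` (recycled); the rest are null (h2 = 0 unless `null_h2` > 0, in
# which case null-gamma genes still have a real eQTL, so their prediction
# models are trainable but carry no risk).
make_architectures <- function(n_genes, n_causal = n_genes, h2 = 0.3,
                               gammas = 0, null_h2 = h2, n_snps = 6L,
                               effect = 0.5, chrom = "1",
                               spacing_mb = 2) {
  gammas <- rep_len(gammas, n_causal)
  lapply(seq_len(n_genes), function(i) {
    gid <- sprintf("g%03d", i)
    causal_gene <- i <= n_causal
    h2_i <- if (causal_gene) h2 else null_h2
    causal <- if (h2_i > 0)
      data.frame(snp = paste0(gid, "_s", ceiling(n_snps / 2)),
                 effect = effect)
    gene_architecture(gid, chrom = chrom, tss = as.integer(i * spacing_mb * 1e6),
                      causal_eqtls = causal, h2_cis = h2_i,
                      gamma = if (causal_gene) gammas[i] else 0,
                      n_snps = n_snps)
  })
}

# Prediction models straight from the generative truth (weight = true eQTL
# effect), bypassing training; used for calibration checks of the gene
# statistic itself.
truth_models <- function(architectures, variants) {
  models <- list()
  for (a in architectures) {
    tr <- a$causal_eqtls
    if (is.null(tr) || nrow(tr) == 0) next
    idx <- match(tr$snp, variants$id)
    models[[a$gene_id]] <- structure(
      list(gene_id = a$gene_id,
           weights = data.frame(snp = tr$snp,
                                ref_allele = variants$ref[idx],
                                eff_allele = variants$alt[idx],
                                weight = tr$effect,
                                stringsAsFactors = FALSE),
           mixing = NA_real_, lambda = NA_real_, cv_r2 = a$h2_cis,
           testable = TRUE),
      class = "prediction_model")
  }
  models
}

# Balding-Nichols two-population dosage matrix (independent SNPs), for PCA
# checks without the full cohort machinery.
bn_two_pop <- function(n_per_pop, n_snps, fst, seed) {
  set.seed(seed)
  p <- runif(n_snps, 0.1, 0.9)
  pops <- lapply(1:2, function(k) {
    pk <- rbeta(n_snps, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
    sapply(pk, function(q) rbinom(n_per_pop, 2, q))
  })
  list(dosage = rbind(pops[[1]], pops[[2]]),
       pop = rep(1:2, each = n_per_pop))
}

# Minimal prediction model / covariance pair built by hand.
stub_model <- function(gene_id, snps, weights, ref = "A", eff = "G") {
  structure(list(gene_id = gene_id,
                 weights = data.frame(snp = snps,
                                      ref_allele = rep_len(ref, length(snps)),
                                      eff_allele = rep_len(eff, length(snps)),
                                      weight = weights,
                                      stringsAsFactors = FALSE),
                 mixing = 0.5, lambda = NA_real_, cv_r2 = 0.5,
                 testable = TRUE),
            class = "prediction_model")
}

stub_covariance <- function(gene_id, snps, sigma) {
  dimnames(sigma) <- list(snps, snps)
  structure(list(gene_id = gene_id, snps = snps, sigma = sigma),
            class = "snp_covariance")
}
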