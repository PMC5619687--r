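Package: twasmeta
Title: Trans-Ethnic Gene-Level Expression Association from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A transcriptome-wide association (TWAS) pipeline for multi-ancestry
    case-control studies. Trains per-gene elastic-net expression prediction
    weights on a genotyped reference transcriptome panel, computes
    summary-statistic-based gene-level association Z-scores from per-SNP GWAS
    results and a reference linkage-disequilibrium covariance, combines gene
    results across ancestry groups by sample-size-weighted Z meta-analysis and
    SNP results by fixed-effect inverse-variance meta-analysis with Cochran's Q
    heterogeneity, and applies Benjamini-Hochberg false discovery control and
    known-locus enrichment post-processing. Includes a simulator of ancestry-
    diverged case-control cohorts with expression-mediated genetic risk
    (Balding-Nichols allele-frequency divergence, autoregressive linkage
    disequilibrium) for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
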