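---
title: "Gene-level predicted-expression association across ancestry groups"
author: "twasmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level predicted-expression association across ancestry groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twasmeta)
```

## The model

A transcriptome-wide association study (TWAS) asks whether the
*genetically regulated* component of a gene's expression (GReX) is
associated with a trait. The chain has three links:

1. **Expression prediction.** In a reference panel with both genotypes
   and expression, each gene's expression is regressed on its cis SNP
   dosages with the elastic net, giving per-allele weights
   $w_{lg}$ for gene $g$ and SNP $l$. The mixing parameter is 0.5
   (halfway between ridge and lasso), which spreads weight across
   correlated SNPs and makes the predictor robust when single SNPs are
   missing or monomorphic in a downstream study.
2. **Per-study GWAS.** Each case-control cohort is analyzed SNP by SNP
   with additive logistic regression adjusting for genotype principal
   components, producing log odds ratios $\beta_l$ and standard errors
   $se_l$.
3. **Summary-based gene statistic.** Individual-level genotypes are not
   needed to test the predicted expression: with $\Gamma$ the reference
   covariance of the model SNPs' dosages, $\sigma_l^2 = \Gamma_{ll}$ and
   $\sigma_g^2 = w^\top \Gamma w$ the variance of the predicted
   expression, the gene-level statistic is
   $$ Z_g \;=\; \sum_l w_{lg}\,\frac{\sigma_l}{\sigma_g}\,
      \frac{\beta_l}{se_l}, $$
   approximately standard normal under the null. A positive $Z_g$ means
   higher predicted expression goes with higher risk. This is the
   statistic `gene_zscore()` computes; `run_study_genescan()` applies it
   genome-wide after harmonizing the summary table to the model alleles
   and dropping SNPs that are absent or monomorphic in the study (the
   covariance is restricted to the surviving SNPs, so a six-SNP model
   becomes a five-SNP test in a cohort where one predictor is
   monomorphic).

Studies from different ancestry groups are then combined per gene by the
sample-size-weighted Z method,
$$ Z_{meta} = \frac{\sum_k \sqrt{N_k}\, Z_k}{\sqrt{\sum_k N_k}}, $$
where $N_k$ is the **case-control effective sample size**
$4/(1/N_{cases} + 1/N_{controls})$. The effective (rather than total)
size is the choice that reproduces the bundled study's published
combined Z-scores exactly; with raw totals the top gene's combined
statistic comes out visibly different (−5.00 rather than −5.013), so we
treat the effective-size identification as established by that
reproduction and document it here. Studies in which a gene could not be
tested are omitted from both sums.

SNP-level results are combined by fixed-effect inverse-variance
weighting (`ivw_meta_snp()`), with Cochran's Q against $\chi^2_{K-1}$
for heterogeneity. Published tables often print only an odds ratio and
95% CI; `se_from_ci()` reconstructs the log-scale standard error as
$(\ln hi - \ln lo)/(2 \cdot 1.96)$, using 1.96 rather than a
higher-precision quantile because that is how printed intervals are
formed.

Post-processing is deliberately plain: Bonferroni thresholds
($\alpha/m$), Benjamini-Hochberg step-up FDR (`bh_adjust()`, which
accepts a total test count $m$ larger than the list supplied, valid when
the unlisted p-values are larger), QQ coordinates on the $-\log_{10}$
scale with the $(i-0.5)/n$ expected quantiles, and a known-locus
enrichment test. The enrichment test is the Pearson chi-square on the
2×2 near-locus × significant table **without** continuity correction —
the only standard 2×2 test that reproduces both of the bundled study's
printed enrichment p-values (0.044 and 0.75) from its printed counts.

## What the simulator emulates — and what it does not

`simulate_reference_panel()` and `simulate_cohort()` generate the
structure the analysis assumes:

* **Genotypes** are two latent-Gaussian haplotypes thresholded at the
  allele frequency; within a gene's SNP block the latent process is
  AR(1) with correlation `ld_block_rho` (default 0.7), giving tunable
  local LD. Blocks for different genes are independent.
* **Ancestry divergence** follows the Balding-Nichols construction:
  cohort frequencies are Beta draws with mean equal to the ancestral
  frequency and variance $p(1-p)F_{st}$. Cohort-specific monomorphic
  SNPs can be forced (dosage variance exactly zero), mirroring
  predictors that drop out of one population.
* **Expression** is the causal-eQTL dosage combination plus Gaussian
  noise scaled so the genetic fraction of expression variance equals
  `h2_cis`.
* **Disease** follows a liability model on the logit scale: intercept
  calibrated to 10% prevalence, plus `gamma` per standard deviation of
  *true* GReX (not total expression — the estimand the pipeline tests),
  plus a per-ancestry offset. Exact case/control counts are filled by
  rejection sampling with a budget of 100× the target size.

Not emulated: recombination maps (LD is a single AR parameter, not a
map), imputation uncertainty (dosages are integer), the X chromosome,
cryptic relatedness, and real covariate structure (age is noise, the PC
surrogate is a shifted Gaussian). Passing tests therefore show the
statistics behave as derived **under the model's own assumptions**; they
do not certify behavior under real-data pathologies such as imputation
artifacts or fine-scale stratification.

## Defaults and numerical choices

| Parameter | Default | Why |
|---|---|---|
| MAF threshold | 0.05, strict `>` | predictors and tests restricted to common variants; strictness recorded by test |
| cis window | 1 Mb from TSS | covers published predictor spans (hundreds of kb) with margin |
| elastic-net mixing | 0.5 | robustness to missing/low-quality genotypes (see above) |
| CV folds / penalty | 10 folds, ~100-value log grid, min-MSE rule | standard cross-validation; 1-SE rule off |
| weak-model cutoff | CV $R^2 \le 0.01$ | genes below it are flagged untestable and skipped |
| PCs per study | 4 (configurable) | the covariate role matters, not the PCA algorithm; plain standardized-genotype PCA, no LD pruning or outlier loops |
| IRLS | tol $10^{-8}$, max 50 iterations | separation or non-convergence yields a missing record, never aborts a scan |
| locus window | 250 kb, gene-body distance, inclusive boundary | "within" a window is read inclusively; gene-body (not TSS-only) distance is the more conservative reading |
| liability prevalence | 10% | a realistic disease prevalence for a common cancer over a lifetime horizon |
| CI quantile | 1.96 | matches printed CI arithmetic |

Degenerate inputs are handled explicitly: a heritable gene with no
causal eQTLs is an error at simulation; a gene model with zero usable
SNPs, or $w^\top \Gamma w \le 0$, yields a missing-value record excluded
from meta-analysis; a constant dosage column is an error for a single
fit but simply filtered in a genome scan; strand-ambiguous (A/T, C/G)
SNPs are kept with a warning flag by default — the simulator is
strand-consistent — and can be dropped by option, since their correct
handling in external data is study-specific.

## Validation design and problem sizes

The test suite validates each claim at the smallest size that gives a
stable answer, chosen once as the package's study conditions:

* **Oracle equivalence.** The defining property of the summary-based
  statistic is that it recovers the individual-level test. On a cohort
  of 2,000 (200 genes, reference panel of 900), the correlation between
  $Z_g$ and the Wald Z from logistic regression of case status on
  individually predicted expression (same weights, same covariates)
  exceeds 0.99.
* **Calibration.** With all `gamma = 0` (1,000 genes, cohort of 1,000),
  gene-level p-values are uniform (Kolmogorov-Smirnov) and SNP-level
  type-I error at 0.05 is nominal within ±0.01.
* **Recovery.** Genes with $|\gamma| = 0.3$, $h^2_{cis} = 0.3$, cohorts
  of 4,000: the association sign is recovered and the gene ranks within
  the top 5% genome-wide in the overwhelming majority of 12 seeds.
* **Reproduction.** Every combined cell of the bundled study tables is
  recomputed from its per-study cells: gene-level totals to ±0.005 on
  the Z scale, SNP-level meta rows to ±0.01 on the OR/CI scale
  (rounding of printed inputs). Two published ER-negative SNP cells are
  internally inconsistent with their own printed p-values; for those the
  reconstruction is checked against the printed p instead, as noted in
  the reproduction test.
* **Invariances.** $Z_g$ is invariant to rescaling a gene's weights, to
  allele-flipping a summary row (after harmonization), and to SNP order;
  $Z_{meta}$ to study order and to rescaling all effective sizes;
  covariances are symmetric positive semi-definite; BH output is
  monotone and bounded below by the raw p-values.

`scripts/acceptance.R` recomputes the headline combined statistics from
the bundled per-study tables alone and writes them as JSON; see the
README for how to run it.

## Known limitations

* The reference covariance comes from the training panel, not the study
  cohort — the defining approximation of the summary-based setting. The
  oracle-equivalence test quantifies agreement when ancestries match;
  under strong mismatch the covariance misspecifies the LD and $Z_g$
  degrades gracefully rather than provably.
* The simulator's free knobs (LD strength, frequency ranges, covariate
  structure) are realistic but not estimates of any particular cohort.
* Which genes are "testable" is data-determined (weak-model cutoff), so
  genome-wide testable counts are not comparable across datasets.
* Gene-level meta-analysis assumes per-study Z-scores are computed on
  the same allele orientation and weight set; `harmonize()` enforces
  this within the pipeline but cannot audit externally supplied gene
  tables.
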