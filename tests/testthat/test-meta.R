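test_that("effective sample size evaluates the case-control formula", {
  expect_equal(effective_n(500, 500), 1000, tolerance = 1e-12)
  expect_lt(abs(effective_n(988, 2745) - 2906.0), 0.1)
  expect_lt(abs(effective_n(1998, 3263) - 4956.8), 0.1)
})

test_that("gene Z meta-analysis combines studies by root-Neff weights", {
  fx <- load_study_fixtures()
  ne <- fixture_effective_n("er_negative")
  per <- subset(fx$genes, phenotype == "er_negative" & study != "Total" &
                  gene == "TP53INP2")
  mz <- meta_z_genes(per[, c("gene", "study", "zscore")], ne)
  expect_equal(mz$zscore, -5.013, tolerance = 5e-3)
  # single study: identity
  one <- meta_z_genes(data.frame(gene = "g", study = "A", zscore = 1.7),
                      c(A = 1000))
  expect_equal(one$zscore, 1.7, tolerance = 1e-12)
  # study order invariance and Neff scale invariance
  rev <- meta_z_genes(per[rev(seq_len(nrow(per))),
                          c("gene", "study", "zscore")], ne)
  expect_equal(rev$zscore, mz$zscore, tolerance = 1e-12)
  sc <- meta_z_genes(per[, c("gene", "study", "zscore")], ne * 17)
  expect_equal(sc$zscore, mz$zscore, tolerance = 1e-12)
  # a study missing the gene drops out of both sums
  per$zscore[per$study == "BPC3"] <- NA
  loo <- meta_z_genes(per[, c("gene", "study", "zscore")], ne)
  expect_equal(loo$zscore, -4.127, tolerance = 5e-3)
  expect_identical(loo$n_studies, 3L)
  # zero contributing studies: missing record
  none <- meta_z_genes(data.frame(gene = "g", study = "A",
                                  zscore = NA_real_), c(A = 10))
  expect_true(is.na(none$zscore))
  expect_identical(none$n_studies, 0L)
})

test_that("standard errors reconstructed from printed confidence intervals", {
  expect_lt(abs(se_from_ci(1.29, 1.12, 1.50) - 0.0745), 5e-5)
  se <- se_from_ci(1.00, 0.80, 1.25)
  expect_lt(abs(se - 0.1139), 1e-4)
  expect_equal(log(1.00), (log(0.80) + log(1.25)) / 2, tolerance = 1e-12)
  expect_identical(se_from_ci(1, 1.2, 1.2), 0)
  expect_error(se_from_ci(1, -1, 2), "positive")
})

test_that("inverse-variance meta-analysis matches its replication limit", {
  k <- 4
  out <- ivw_meta_snp(rep(0.3, k), rep(0.1, k))
  expect_equal(out$beta, 0.3, tolerance = 1e-12)
  expect_equal(out$se, 0.1 / sqrt(k), tolerance = 1e-12)
  expect_equal(out$q, 0, tolerance = 1e-12)
  out2 <- ivw_meta_snp(c(0.1, 0.4), c(0.05, 0.2))
  expect_lte(out2$se, 0.05)
  expect_equal(out2$ci_low, exp(out2$beta - 1.96 * out2$se),
               tolerance = 1e-12)
  expect_error(ivw_meta_snp(numeric(), numeric()), "no studies")
})

test_that("inverse-variance combination agrees with an independent fixed-effect fit", {
  skip_if_not_installed("metafor")
  set.seed(62)
  for (i in 1:5) {
    b <- rnorm(4, 0.2, 0.3)
    s <- runif(4, 0.05, 0.3)
    ours <- ivw_meta_snp(b, s)
    ref <- metafor::rma(yi = b, sei = s, method = "FE")
    expect_equal(ours$beta, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(ours$se, ref$se, tolerance = 1e-10)
    expect_equal(ours$q, ref$QE, tolerance = 1e-10)
    expect_equal(ours$p_het, ref$QEp, tolerance = 1e-10)
  }
})

test_that("Cochran's Q detects and quantifies heterogeneity", {
  expect_equal(cochran_q(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.3))$q, 0,
               tolerance = 1e-12)
  expect_equal(cochran_q(c(0.2, 0.2), c(0.1, 0.1))$p_het, 1,
               tolerance = 1e-12)
  expect_equal(cochran_q(c(0, 3), c(1, 1))$q, 4.5, tolerance = 1e-12)
  expect_true(is.na(cochran_q(0.5, 0.1)$q))
})

test_that("every bundled combined cell reproduces from its per-study cells", {
  fx <- load_study_fixtures()
  # gene-level totals, both phenotypes, within printed-input rounding
  for (ph in c("overall", "er_negative")) {
    ne <- fixture_effective_n(ph)
    g <- subset(fx$genes, phenotype == ph)
    mz <- meta_z_genes(subset(g, study != "Total")[,
                         c("gene", "study", "zscore")], ne)
    tot <- subset(g, study == "Total")
    expect_lt(max(abs(mz$zscore[match(tot$gene, mz$gene)] - tot$zscore)),
              5e-3)
  }
  # SNP-level meta rows. Two published ER-negative cells (rs8116198,
  # rs6058107) disagree with their own printed p-values; for those the
  # reconstruction is checked against the printed p instead of the CI.
  inconsistent <- c("rs8116198", "rs6058107")
  for (ph in c("overall", "er_negative")) {
    per <- subset(fx$snps, phenotype == ph & study != "meta")
    met <- subset(fx$snps, phenotype == ph & study == "meta")
    mm <- meta_snp_table(per)
    i <- match(met$snp, mm$snp)
    ok <- if (ph == "er_negative") !met$snp %in% inconsistent
          else rep(TRUE, nrow(met))
    expect_lt(max(abs(mm$or[i][ok] - met$or[ok])), 0.011)
    expect_lt(max(abs(mm$ci_low[i][ok] - met$ci_low[ok])), 0.011)
    expect_lt(max(abs(mm$ci_high[i][ok] - met$ci_high[ok])), 0.011)
    expect_lt(max(abs(log10(mm$pvalue[i] / met$pvalue))), 0.35)
    expect_gt(min(mm$p_het[i]), 0.05)  # no significant heterogeneity
  }
  # discovery-phase rows with the European cohort removed
  per <- subset(fx$snps, phenotype == "er_negative" &
                  !study %in% c("meta", "BPC3"))
  mm <- meta_snp_table(per)
  u4c <- subset(fx$replication, phase == "U4C" &
                  phenotype == "er_negative")
  i <- match(u4c$snp, mm$snp)
  expect_lt(max(abs(mm$or[i] - u4c$or)), 0.011)
})

test_that("fixture lookups return the published records", {
  fx <- load_study_fixtures()
  z <- subset(fx$genes, gene == "TP53INP2" & phenotype == "er_negative" &
                study == "AABC")$zscore
  expect_identical(z, -3.708)
  cc <- subset(fx$cohorts, study == "AABC")
  expect_identical(cc$n_cases_er_negative, 988L)
  expect_identical(cc$n_controls, 2745L)
  r <- subset(fx$snps, snp == "rs1205339" & phenotype == "er_negative" &
                study == "SBCGS")
  expect_identical(c(r$or, r$ci_low, r$ci_high), c(1.06, 0.89, 1.26))
})
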