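summary_row <- function(snp, a1, a2, beta, se = 0.1, freq = 0.3) {
  data.frame(SNP = snp, CHR = "1", POS = 1, A1 = a1, A2 = a2, FREQ1 = freq,
             BETA = beta, SE = se, P = 2 * pnorm(-abs(beta / se)),
             N_CASES = 100, N_CONTROLS = 100, stringsAsFactors = FALSE)
}

test_that("harmonization keeps, flips or drops summary records by allele", {
  mod <- stub_model("g", c("s1", "s2", "s3", "s4"), c(1, 1, 1, 1),
                    ref = c("A", "A", "A", "A"),
                    eff = c("G", "G", "T", "G"))
  ss <- rbind(summary_row("s1", "G", "A", 0.25),        # match
              summary_row("s2", "A", "G", 0.25),        # swapped
              summary_row("s3", "T", "A", 0.10),        # ambiguous A/T
              summary_row("s4", "C", "T", 0.10))        # incompatible
  h <- suppressWarnings(harmonize(ss, mod))
  expect_equal(h$beta[h$snp == "s1"], 0.25)
  expect_equal(h$freq[h$snp == "s1"], 0.3)
  expect_equal(h$beta[h$snp == "s2"], -0.25)
  expect_equal(h$freq[h$snp == "s2"], 0.7)
  expect_true(h$ambiguous[h$snp == "s3"])
  dropped <- attr(h, "dropped")
  expect_identical(dropped$reason[dropped$snp == "s4"], "allele_mismatch")
  h2 <- harmonize(ss, mod, drop_ambiguous = TRUE)
  expect_false("s3" %in% h2$snp)
  d2 <- attr(h2, "dropped")
  expect_identical(d2$reason[d2$snp == "s3"], "ambiguous")
})

test_that("model reduction mirrors a study-monomorphic predictor SNP", {
  snps <- paste0("s", 1:6)
  sg <- diag(6) * 0.4 + 0.05
  mod <- stub_model("g", snps, rep(0.2, 6))
  cv <- stub_covariance("g", snps, sg)
  red <- reduce_model(mod, cv, snps[-3])  # one SNP monomorphic in study
  expect_identical(red$n_model_snps, 6L)
  expect_identical(red$n_snps_used, 5L)
  expect_identical(dim(red$covariance$sigma), c(5L, 5L))
  full <- reduce_model(mod, cv, snps)
  expect_identical(full$model$weights, mod$weights)
  none <- reduce_model(mod, cv, character(0))
  expect_identical(none$n_snps_used, 0L)
  rec <- gene_zscore(none$model, none$covariance,
                     data.frame(snp = character(), zscore = numeric()),
                     study = "S", n_model_snps = none$n_model_snps)
  expect_true(is.na(rec$zscore))
  expect_identical(rec$n_snps_used, 0L)
})

test_that("the gene Z-score matches its defining formula", {
  # single SNP: sigma_g = |w| sigma_l, so Z = sign(w) * beta/se
  m1 <- stub_model("g", "s1", -2)
  c1 <- stub_covariance("g", "s1", matrix(0.5))
  h1 <- data.frame(snp = "s1", zscore = 2.5)
  expect_equal(gene_zscore(m1, c1, h1)$zscore, -2.5, tolerance = 1e-12)
  # w = (1,1), Gamma = [[1,.5],[.5,1]], z = (2,3) -> 5/sqrt(3)
  m2 <- stub_model("g", c("s1", "s2"), c(1, 1))
  c2 <- stub_covariance("g", c("s1", "s2"),
                        matrix(c(1, 0.5, 0.5, 1), 2))
  h2 <- data.frame(snp = c("s1", "s2"), zscore = c(2, 3))
  r2 <- gene_zscore(m2, c2, h2)
  expect_equal(r2$zscore, 5 / sqrt(3), tolerance = 1e-12)
  expect_equal(r2$zscore, 2.887, tolerance = 1e-3)
  expect_equal(r2$sigma_g, sqrt(3), tolerance = 1e-12)
  expect_equal(r2$pvalue, 2 * pnorm(-abs(r2$zscore)), tolerance = 1e-15)
  # all null betas
  h0 <- data.frame(snp = c("s1", "s2"), zscore = c(0, 0))
  r0 <- gene_zscore(m2, c2, h0)
  expect_identical(r0$zscore, 0)
  expect_identical(r0$pvalue, 1)
  # degenerate covariance yields a missing record, not an error
  cd <- stub_covariance("g", c("s1", "s2"), matrix(0, 2, 2))
  expect_true(is.na(gene_zscore(m2, cd, h2)$zscore))
})

test_that("gene Z is invariant to weight scale, allele flips and SNP order", {
  set.seed(61)
  snps <- paste0("s", 1:4)
  A <- matrix(rnorm(16), 4)
  sg <- crossprod(A) + diag(4) * 0.1
  w <- c(0.4, -0.2, 0.1, 0.3)
  mod <- stub_model("g", snps, w)
  cv <- stub_covariance("g", snps, sg)
  ss <- do.call(rbind, lapply(1:4, function(i)
    summary_row(snps[i], "G", "A", rnorm(1, 0, 0.2))))
  z0 <- gene_zscore(mod, cv, harmonize(ss, mod))$zscore
  # weight scale
  mods <- stub_model("g", snps, 7 * w)
  expect_equal(gene_zscore(mods, cv, harmonize(ss, mods))$zscore, z0,
               tolerance = 1e-12)
  # allele flip of one summary row, beta negated, restored by harmonization
  ssf <- ss
  ssf[2, c("A1", "A2")] <- c("A", "G")
  ssf$BETA[2] <- -ssf$BETA[2]
  ssf$FREQ1[2] <- 1 - ssf$FREQ1[2]
  expect_equal(gene_zscore(mod, cv, harmonize(ssf, mod))$zscore, z0,
               tolerance = 1e-12)
  # SNP order permutation of the model (and its covariance)
  perm <- c(3, 1, 4, 2)
  modp <- stub_model("g", snps[perm], w[perm])
  cvp <- stub_covariance("g", snps[perm], sg[perm, perm])
  expect_equal(gene_zscore(modp, cvp, harmonize(ss, modp))$zscore, z0,
               tolerance = 1e-12)
})

test_that("a study gene scan handles empty databases and logs reductions", {
  ss <- summary_row("s1", "G", "A", 0.2)
  empty <- run_study_genescan(ss, list(), list(), study = "S")
  expect_identical(nrow(empty), 0L)
  mod <- stub_model("g", c("s1", "sX"), c(1, 1))
  cv <- stub_covariance("g", c("s1", "sX"), diag(2) * 0.4)
  out <- run_study_genescan(ss, list(g = mod), list(g = cv), study = "S")
  expect_identical(out$n_snps_used, 1L)
  expect_identical(attr(out, "reductions")$g$reason, "absent")
})
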