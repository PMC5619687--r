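test_that("a pure-noise gene is flagged weak; causal SNPs are recovered", {
  arch <- make_architectures(2, n_causal = 1, h2 = 0.5, gammas = 0,
                             null_h2 = 0)
  panel <- simulate_reference_panel(900, arch, seed = 51)
  null_mod <- train_elastic_net(panel, "g002", seed = 1)
  expect_false(null_mod$testable)
  expect_lte(null_mod$cv_r2, 0.01)
  hits <- 0
  for (s in 1:10) {
    panel_s <- simulate_reference_panel(900, arch, seed = 500 + s)
    m <- train_elastic_net(panel_s, "g001", seed = 1)
    if (nrow(m$weights)) {
      top <- m$weights$snp[which.max(abs(m$weights$weight))]
      ok <- top == arch[[1]]$causal_eqtls$snp &&
        sign(m$weights$weight[m$weights$snp == top]) ==
          sign(arch[[1]]$causal_eqtls$effect)
      hits <- hits + ok
    }
  }
  expect_gte(hits, 9)
})

test_that("training records the elastic-net mixing parameter", {
  arch <- make_architectures(1, h2 = 0.4, gammas = 0)
  panel <- simulate_reference_panel(200, arch, seed = 52)
  m <- train_elastic_net(panel, "g001", seed = 1)
  expect_identical(m$mixing, 0.5)
  expect_true(m$cv_r2 >= 0 && m$cv_r2 <= 1)
})

test_that("doubling expression doubles the weights on the matched penalty path", {
  arch <- make_architectures(1, h2 = 0.4, gammas = 0)
  panel <- simulate_reference_panel(400, arch, seed = 53)
  m1 <- train_elastic_net(panel, "g001", seed = 2)
  panel2 <- panel
  panel2$expression <- panel$expression * 2
  m2 <- train_elastic_net(panel2, "g001", seed = 2)
  expect_identical(m1$weights$snp, m2$weights$snp)
  expect_equal(m2$weights$weight, 2 * m1$weights$weight, tolerance = 1e-4)
})

test_that("reference covariance matches hand-computed sample covariance", {
  dos <- cbind(s1 = c(0, 1, 2), s2 = c(2, 1, 0))
  mod <- stub_model("g", c("s1", "s2"), c(1, 1))
  cv <- build_covariance(dos, mod)
  expect_equal(unname(cv$sigma), matrix(c(1, -1, -1, 1), 2),
               tolerance = 1e-12)
  one <- build_covariance(dos, stub_model("g1", "s1", 0.5))
  expect_equal(unname(one$sigma), matrix(var(c(0, 1, 2))),
               tolerance = 1e-12)
  expect_error(build_covariance(dos, stub_model("g2", "s9", 1)), "s9")
})

test_that("independent SNPs have near-zero off-diagonal covariance", {
  set.seed(54)
  dos <- cbind(a = rbinom(10000, 2, 0.3), b = rbinom(10000, 2, 0.6))
  cv <- build_covariance(dos, stub_model("g", c("a", "b"), c(1, 1)))
  expect_lt(abs(cv$sigma[1, 2]),
            0.05 * sqrt(cv$sigma[1, 1] * cv$sigma[2, 2]))
})

test_that("trained covariances are symmetric and positive semi-definite", {
  arch <- make_architectures(3, h2 = 0.4, gammas = 0)
  panel <- simulate_reference_panel(300, arch, seed = 55)
  for (a in arch) {
    m <- train_elastic_net(panel, a$gene_id, seed = 1)
    if (!nrow(m$weights)) next
    cv <- build_covariance(panel, m)
    expect_equal(cv$sigma, t(cv$sigma), tolerance = 1e-12)
    expect_gte(min(eigen(cv$sigma, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("the model database round-trips losslessly in stable order", {
  arch <- make_architectures(3, h2 = 0.4, gammas = 0)
  panel <- simulate_reference_panel(300, arch, seed = 56)
  models <- covs <- list()
  for (a in arch) {
    m <- train_elastic_net(panel, a$gene_id, seed = 1)
    m$weights <- m$weights[order(m$weights$snp), ]
    rownames(m$weights) <- NULL
    models[[a$gene_id]] <- m
    covs[[a$gene_id]] <- build_covariance(panel, m)
  }
  wp <- withr::local_tempfile(fileext = ".tsv")
  cp <- withr::local_tempfile(fileext = ".tsv")
  write_model_db(models, covs, wp, cp)
  db <- read_model_db(wp, cp)
  for (g in names(models)) {
    expect_equal(db$models[[g]]$weights, models[[g]]$weights,
                 tolerance = 1e-12)
    expect_equal(db$models[[g]]$cv_r2, models[[g]]$cv_r2,
                 tolerance = 1e-12)
    expect_equal(db$covariances[[g]]$sigma[covs[[g]]$snps, covs[[g]]$snps,
                                           drop = FALSE],
                 covs[[g]]$sigma, tolerance = 1e-12)
  }
  # covariance file rows are (gene, snp_i, snp_j) sorted, hence stable
  cvtab <- read.delim(cp)
  key <- paste(cvtab$GENE, cvtab$RSID1, cvtab$RSID2)
  expect_identical(key, sort(key))
  # a second write is byte-identical
  wp2 <- withr::local_tempfile(fileext = ".tsv")
  cp2 <- withr::local_tempfile(fileext = ".tsv")
  write_model_db(models, covs, wp2, cp2)
  expect_identical(readLines(cp), readLines(cp2))
  expect_identical(unname(tools::md5sum(wp)), unname(tools::md5sum(wp2)))
})
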