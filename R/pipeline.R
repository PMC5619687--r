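# End-to-end orchestration: simulate -> per-study GWAS -> train models ->
# per-study gene scan -> meta-analysis -> post-processing, under one seed,
# with provenance headers on every output table.

#' Assemble a pipeline configuration
#'
#' @param architectures List of [gene_architecture()] objects defining the
#'   simulated transcriptome.
#' @param cohorts List of [cohort_spec()] objects (one GWAS per cohort).
#' @param out_dir Output directory.
#' @param panel_n Reference panel size (default 900, a whole-blood-panel
#'   scale).
#' @param maf_threshold MAF cutoff applied in training and in each study.
#' @param k_pcs Principal components adjusted for per study.
#' @param cis_window Cis window around the TSS in base pairs.
#' @param mixing Elastic-net mixing parameter.
#' @param folds Cross-validation folds.
#' @param ld_block_rho Latent AR(1) LD correlation for the simulator.
#' @param locus_catalog Optional data.frame (`locus_id`, `chrom`, `pos`)
#'   of known susceptibility loci for the enrichment report.
#' @param locus_window Base-pair proximity window (default 250 kb).
#' @param alpha Significance level for Bonferroni/enrichment (default 0.05).
#' @param seed Master seed; all stage seeds derive from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(architectures, cohorts, out_dir,
                            panel_n = 900L, maf_threshold = 0.05,
                            k_pcs = 4L, cis_window = 1e6, mixing = 0.5,
                            folds = 10L, ld_block_rho = 0.7,
                            locus_catalog = NULL, locus_window = 250000,
                            alpha = 0.05, seed = 1L) {
  stopifnot(length(architectures) > 0, length(cohorts) > 0,
            maf_threshold >= 0, maf_threshold < 0.5,
            mixing >= 0, mixing <= 1, alpha > 0, alpha < 1,
            locus_window >= 0, is.numeric(seed))
  structure(list(architectures = architectures, cohorts = cohorts,
                 out_dir = out_dir, panel_n = as.integer(panel_n),
                 maf_threshold = maf_threshold, k_pcs = as.integer(k_pcs),
                 cis_window = cis_window, mixing = mixing,
                 folds = as.integer(folds), ld_block_rho = ld_block_rho,
                 locus_catalog = locus_catalog,
                 locus_window = locus_window, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

.write_prov_tsv <- function(df, path, prov) {
  cat(prov, "\n", sep = "", file = path)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates the reference panel and cohorts, runs the per-study SNP GWAS,
#' trains per-gene elastic-net models and reference covariances, scores
#' every gene per study from the summary statistics, combines studies by
#' effective-sample-size-weighted Z meta-analysis, and writes the
#' post-processing report (Bonferroni threshold, BH-adjusted values, QQ
#' coordinates, optional known-locus enrichment). Every output table
#' starts with a `#` provenance line holding the config hash and seed;
#' re-running with an identical configuration reproduces identical files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `summaries` (per-study summary tables),
#'   `gene_tables` (per-study gene scans), `meta` (combined gene table
#'   with BH-adjusted values), `models`, `covariances`, `enrichment`
#'   (or `NULL`), and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  prov <- paste0("# twasmeta ",
                 as.character(utils::packageVersion("twasmeta")),
                 " config=", hash, " seed=", config$seed)
  arch <- config$architectures
  variants <- build_variant_table(arch)

  panel <- simulate_reference_panel(config$panel_n, arch,
                                    ld_block_rho = config$ld_block_rho,
                                    seed = config$seed, variants = variants)
  models <- covs <- list()
  for (a in arch) {
    m <- train_elastic_net(panel, a$gene_id, cis_window = config$cis_window,
                           mixing = config$mixing, folds = config$folds,
                           seed = config$seed,
                           maf_threshold = config$maf_threshold)
    models[[a$gene_id]] <- m
    if (nrow(m$weights)) covs[[a$gene_id]] <- build_covariance(panel, m)
  }
  write_model_db(models[vapply(models, function(m) nrow(m$weights) > 0,
                               TRUE)],
                 covs, file.path(config$out_dir, "weights.tsv"),
                 file.path(config$out_dir, "covariances.tsv"))

  summaries <- gene_tables <- list()
  neff <- numeric()
  for (i in seq_along(config$cohorts)) {
    spec <- config$cohorts[[i]]
    cohort <- simulate_cohort(spec, arch, variants = variants,
                              ld_block_rho = config$ld_block_rho,
                              seed = config$seed + i)
    ss <- run_study_gwas(cohort, k_pcs = config$k_pcs,
                         maf_threshold = config$maf_threshold)
    .write_prov_tsv(ss, file.path(config$out_dir,
                                  paste0("summary_", spec$name, ".tsv")),
                    prov)
    gt <- run_study_genescan(ss, models, covs, study = spec$name,
                             maf_threshold = config$maf_threshold)
    .write_prov_tsv(gt, file.path(config$out_dir,
                                  paste0("genes_", spec$name, ".tsv")),
                    prov)
    summaries[[spec$name]] <- ss
    gene_tables[[spec$name]] <- gt
    neff[spec$name] <- effective_n(spec$n_cases, spec$n_controls)
  }

  meta <- meta_z_genes(do.call(rbind, gene_tables), neff)
  ok <- is.finite(meta$pvalue)
  meta$fdr <- NA_real_
  meta$fdr[ok] <- bh_adjust(meta$pvalue[ok])
  meta$bonferroni <- bonferroni_threshold(sum(ok), config$alpha)
  .write_prov_tsv(meta, file.path(config$out_dir, "meta_genes.tsv"), prov)
  .write_prov_tsv(qq_points(meta$pvalue[ok]),
                  file.path(config$out_dir, "qq_genes.tsv"), prov)

  enr <- NULL
  if (!is.null(config$locus_catalog)) {
    gl <- data.frame(
      gene = vapply(arch, `[[`, "", "gene_id"),
      chrom = vapply(arch, `[[`, "", "chrom"),
      start = vapply(arch, function(a) min(a$tss, a$gene_end), 0L),
      end = vapply(arch, function(a) max(a$tss, a$gene_end), 0L),
      stringsAsFactors = FALSE)
    gl <- gl[gl$gene %in% meta$gene[ok], ]
    near <- classify_proximity(gl, config$locus_catalog,
                               config$locus_window)
    sig <- meta$pvalue[match(gl$gene, meta$gene)] < config$alpha
    enr <- enrichment_chi2(sum(near & sig), sum(near & !sig),
                           sum(!near & sig), sum(!near & !sig))
    .write_prov_tsv(data.frame(near_sig = enr$a, near_nonsig = enr$b,
                               far_sig = enr$c, far_nonsig = enr$d,
                               chisq = enr$chisq, pvalue = enr$pvalue),
                    file.path(config$out_dir, "enrichment.tsv"), prov)
  }
  invisible(list(summaries = summaries, gene_tables = gene_tables,
                 meta = meta, models = models, covariances = covs,
                 enrichment = enr, out_dir = config$out_dir))
}
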