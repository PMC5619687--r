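# Simulation of a reference transcriptome panel and ancestry-diverged
# case-control cohorts with expression-mediated genetic risk.
#
# Genotypes are diploid dosages built from two latent haplotypes; within a
# gene's SNP block the latent Gaussians follow an AR(1) process so that
# corr(SNP_i, SNP_j) ~ rho^|i-j| on the latent scale. Ancestry divergence
# follows the Balding-Nichols construction: cohort-specific allele
# frequencies are Beta draws with mean equal to the ancestral frequency and
# variance p(1-p)*Fst.

#' Describe an ancestry group
#'
#' @param label Short unique label, e.g. `"AFR"`.
#' @param fst Balding-Nichols divergence coefficient from the shared
#'   ancestral population, in `[0, 1)`. `0` means no divergence.
#' @param pc_shift Per-ancestry offset added to the disease liability and
#'   reflected in the cohort's principal-component surrogate covariate
#'   (arbitrary units).
#' @return An object of class `ancestry_spec`.
#' @export
ancestry_spec <- function(label, fst = 0, pc_shift = 0) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.numeric(fst) || length(fst) != 1L || fst < 0 || fst >= 1)
    stop("`fst` must be a single value in [0, 1)", call. = FALSE)
  structure(list(label = label, fst = fst, pc_shift = pc_shift),
            class = "ancestry_spec")
}

#' Describe a case-control cohort
#'
#' @param name Cohort name (used as the study label downstream).
#' @param ancestry An [ancestry_spec()].
#' @param n_cases,n_controls Target counts, both at least 1.
#' @param monomorphic_snps Variant ids forced to dosage 0 for every
#'   individual in this cohort (ancestry-specific monomorphism).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, ancestry, n_cases, n_controls,
                        monomorphic_snps = character()) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(ancestry, "ancestry_spec"))
  if (n_cases < 1 || n_controls < 1)
    stop("`n_cases` and `n_controls` must both be >= 1", call. = FALSE)
  structure(list(name = name, ancestry = ancestry,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 monomorphic_snps = as.character(monomorphic_snps)),
            class = "cohort_spec")
}

#' Describe the genetic architecture of one gene
#'
#' Each gene owns a block of `n_snps` cis variants, with ids
#' `<gene_id>_s1 ... <gene_id>_s<n_snps>`, placed symmetrically around the
#' transcription start site. A subset of these may be causal eQTLs.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome label.
#' @param tss,gene_end 1-based transcription start and gene end.
#' @param causal_eqtls `NULL`, or a data.frame with columns `snp` (ids from
#'   this gene's block) and `effect` (per-allele effect on expression).
#' @param h2_cis Fraction of expression variance explained by cis genotype,
#'   in `[0, 1]`.
#' @param gamma Log-odds effect of one standard deviation of
#'   genetically-regulated expression on disease risk.
#' @param n_snps Number of cis SNPs in the gene's block.
#' @param snp_spacing Base pairs between adjacent block SNPs.
#' @return An object of class `gene_architecture`.
#' @export
gene_architecture <- function(gene_id, chrom, tss, gene_end = tss + 10000L,
                              causal_eqtls = NULL, h2_cis = 0, gamma = 0,
                              n_snps = 10L, snp_spacing = 10000L) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, tss >= 1,
            gene_end >= tss, n_snps >= 1)
  if (h2_cis < 0 || h2_cis > 1)
    stop("`h2_cis` must lie in [0, 1]", call. = FALSE)
  ids <- paste0(gene_id, "_s", seq_len(n_snps))
  if (!is.null(causal_eqtls)) {
    stopifnot(is.data.frame(causal_eqtls),
              all(c("snp", "effect") %in% names(causal_eqtls)))
    bad <- setdiff(causal_eqtls$snp, ids)
    if (length(bad))
      stop("causal eQTLs outside the gene's cis block: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 tss = as.integer(tss), gene_end = as.integer(gene_end),
                 causal_eqtls = causal_eqtls, h2_cis = h2_cis, gamma = gamma,
                 snp_ids = ids, n_snps = as.integer(n_snps),
                 snp_spacing = as.integer(snp_spacing)),
            class = "gene_architecture")
}

#' Build the shared variant table for a set of gene architectures
#'
#' Panel and cohorts simulated from the same architectures must share one
#' variant table; the default `seed` makes the table a deterministic
#' function of the architectures alone, so independent calls agree.
#'
#' @param architectures List of [gene_architecture()] objects.
#' @param freq_range Range of ancestral allele frequencies to draw from.
#' @param seed Integer seed controlling frequencies and allele letters.
#' @return data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `freq` (ancestral effect-allele frequency) and `gene`.
#' @export
build_variant_table <- function(architectures, freq_range = c(0.1, 0.9),
                                seed = 20240601L) {
  stopifnot(length(architectures) > 0,
            all(vapply(architectures, inherits, TRUE, "gene_architecture")))
  ids <- unlist(lapply(architectures, `[[`, "gene_id"))
  if (anyDuplicated(ids))
    stop("duplicated gene_id in architectures", call. = FALSE)
  set.seed(seed)
  # strand-unambiguous ref/alt pairs only; harmonization tests add A/T cases
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                  byrow = TRUE)
  res <- lapply(architectures, function(a) {
    offs <- (seq_len(a$n_snps) - (a$n_snps + 1) / 2) * a$snp_spacing
    pick <- sample.int(nrow(pairs), a$n_snps, replace = TRUE)
    data.frame(id = a$snp_ids, chrom = a$chrom,
               pos = as.integer(round(a$tss + offs)),
               ref = pairs[pick, 1], alt = pairs[pick, 2],
               freq = runif(a$n_snps, freq_range[1], freq_range[2]),
               gene = a$gene_id, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Dosages for one LD block: two haplotypes thresholded from AR(1) latent
# Gaussians. `freq` is the per-SNP effect-allele (alt) frequency.
.sim_block_dosage <- function(n, freq, rho) {
  m <- length(freq)
  thr <- qnorm(freq)
  hap <- function() {
    z <- matrix(0, n, m)
    z[, 1] <- rnorm(n)
    if (m > 1) {
      s <- sqrt(1 - rho^2)
      for (j in 2:m) z[, j] <- rho * z[, j - 1] + s * rnorm(n)
    }
    z < matrix(thr, n, m, byrow = TRUE)
  }
  d <- hap() + hap()
  storage.mode(d) <- "double"
  d
}

# Dosage matrix for all blocks at given per-variant frequencies.
.sim_dosages <- function(n, variants, architectures, rho) {
  out <- matrix(0, n, nrow(variants),
                dimnames = list(NULL, variants$id))
  for (a in architectures) {
    idx <- match(a$snp_ids, variants$id)
    out[, idx] <- .sim_block_dosage(n, variants$freq[idx], rho)
  }
  out
}

# Raw genetically-regulated expression (dosage x true eQTL effects),
# centered at the expected dosage 2p.
.grex_raw <- function(dosage, variants, truth) {
  n <- nrow(dosage)
  out <- matrix(0, n, length(truth), dimnames = list(NULL, names(truth)))
  for (g in names(truth)) {
    tr <- truth[[g]]
    if (is.null(tr) || nrow(tr) == 0) next
    idx <- match(tr$snp, variants$id)
    if (anyNA(idx))
      stop("truth refers to unknown variant for gene ", g, call. = FALSE)
    cen <- sweep(dosage[, idx, drop = FALSE], 2, 2 * variants$freq[idx])
    out[, g] <- as.vector(cen %*% tr$effect)
  }
  out
}

# Per-gene true eQTL effect tables from the architectures.
.truth_from_arch <- function(architectures) {
  truth <- lapply(architectures, `[[`, "causal_eqtls")
  names(truth) <- vapply(architectures, `[[`, "", "gene_id")
  truth
}

#' Simulate a genotyped reference transcriptome panel
#'
#' Emulates an expression reference panel (several hundred individuals with
#' genome-wide dosages and expression). Expression of each gene is the sum
#' of its causal cis-eQTL contributions plus Gaussian noise scaled so the
#' genetic fraction of expression variance is approximately `h2_cis`.
#'
#' @param n_samples Number of panel individuals (at least 30).
#' @param architectures List of [gene_architecture()] objects.
#' @param ld_block_rho AR(1) correlation of the latent haplotype process
#'   within a gene block, in `[0, 1)`.
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @param variants Shared variant table; defaults to
#'   [build_variant_table()] of the architectures.
#' @return An object of class `sim_panel`: list with `dosage`
#'   (samples x variants), `variants`, `expression` (samples x genes),
#'   and `architectures`.
#' @export
simulate_reference_panel <- function(n_samples, architectures,
                                     ld_block_rho = 0.7, seed = 1L,
                                     variants = build_variant_table(architectures)) {
  if (n_samples < 30) stop("`n_samples` must be >= 30", call. = FALSE)
  if (ld_block_rho < 0 || ld_block_rho >= 1)
    stop("`ld_block_rho` must lie in [0, 1)", call. = FALSE)
  for (a in architectures)
    if (a$h2_cis > 0 && (is.null(a$causal_eqtls) || nrow(a$causal_eqtls) == 0))
      stop(errorCondition(
        paste0("gene ", a$gene_id, ": h2_cis > 0 but no causal eQTLs"),
        class = c("twasmeta_invalid_architecture", "error", "condition")))
  force(variants)  # the default build seeds its own RNG; settle it first
  set.seed(seed)
  dosage <- .sim_dosages(n_samples, variants, architectures, ld_block_rho)
  rownames(dosage) <- sprintf("panel_%04d", seq_len(n_samples))
  expr <- matrix(0, n_samples, length(architectures),
                 dimnames = list(rownames(dosage),
                                 vapply(architectures, `[[`, "", "gene_id")))
  for (a in architectures) {
    if (a$h2_cis == 0) {
      expr[, a$gene_id] <- rnorm(n_samples)
    } else {
      idx <- match(a$causal_eqtls$snp, variants$id)
      cen <- scale(dosage[, idx, drop = FALSE], scale = FALSE)
      g <- as.vector(cen %*% a$causal_eqtls$effect)
      vg <- var(g)
      ve <- if (vg > 0) vg * (1 - a$h2_cis) / a$h2_cis else 1
      expr[, a$gene_id] <- g + rnorm(n_samples, sd = sqrt(ve))
    }
  }
  structure(list(dosage = dosage, variants = variants, expression = expr,
                 architectures = architectures, seed = seed),
            class = "sim_panel")
}

#' Simulate an ancestry-diverged case-control cohort
#'
#' Cohort allele frequencies diverge from the ancestral frequencies by the
#' Balding-Nichols model with the ancestry's Fst. Disease risk follows a
#' liability model on the logit scale:
#' `logit P(case) = intercept + sum_g gamma_g * GReX_g / sd(GReX_g) + pc_shift`,
#' where GReX is the genetically-regulated expression (dosage times true
#' eQTL effects). The intercept is calibrated to the requested population
#' prevalence and exact case/control counts are filled by rejection
#' sampling with a bounded budget.
#'
#' @param spec A [cohort_spec()].
#' @param architectures List of [gene_architecture()] objects.
#' @param variants Shared variant table (must be the panel's table).
#' @param weights_truth Optional named list (gene -> data.frame `snp`,
#'   `effect`) overriding the architectures' causal eQTL effects.
#' @param ld_block_rho AR(1) latent LD correlation within blocks.
#' @param prevalence Target population prevalence used to set the
#'   liability intercept.
#' @param budget_factor Rejection-sampling budget as a multiple of the
#'   target cohort size.
#' @param seed Integer seed; same `(spec, seed)` reproduces the cohort.
#' @return An object of class `sim_cohort`: list with `dosage`, `variants`
#'   (with cohort-specific `freq`), `phenotype` (1 case / 0 control),
#'   `covariates` (age and a PC surrogate), and `spec`.
#' @export
simulate_cohort <- function(spec, architectures,
                            variants = build_variant_table(architectures),
                            weights_truth = NULL, ld_block_rho = 0.7,
                            prevalence = 0.10, budget_factor = 100L,
                            seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  force(variants)  # the default build seeds its own RNG; settle it first
  set.seed(seed)
  truth <- if (is.null(weights_truth)) .truth_from_arch(architectures)
           else weights_truth
  gammas <- vapply(architectures, `[[`, 0, "gamma")
  names(gammas) <- vapply(architectures, `[[`, "", "gene_id")

  fst <- spec$ancestry$fst
  cvar <- variants
  if (fst > 0) {
    p <- variants$freq
    cvar$freq <- rbeta(length(p), p * (1 - fst) / fst,
                       (1 - p) * (1 - fst) / fst)
  }
  mono <- spec$monomorphic_snps
  if (length(mono)) {
    miss <- setdiff(mono, cvar$id)
    if (length(miss))
      stop("monomorphic_snps not in variant table: ",
           paste(miss, collapse = ", "), call. = FALSE)
    cvar$freq[cvar$id %in% mono] <- 0
  }

  # calibrate the per-gene GReX standard deviation in this cohort
  cal <- .sim_dosages(2000L, cvar, architectures, ld_block_rho)
  grex_sd <- apply(.grex_raw(cal, cvar, truth), 2, sd)
  grex_sd[grex_sd == 0] <- Inf  # genes with no genetic variance contribute 0

  intercept <- qlogis(prevalence)
  n_target <- spec$n_cases + spec$n_controls
  budget <- budget_factor * n_target
  drawn <- 0L
  case_rows <- list(); ctrl_rows <- list()
  n_case <- 0L; n_ctrl <- 0L
  batch <- max(1000L, n_target)
  while (n_case < spec$n_cases || n_ctrl < spec$n_controls) {
    if (drawn >= budget)
      stop(errorCondition(
        paste0("cohort ", spec$name, ": sampling budget (",
               budget, " draws) exhausted before reaching ",
               spec$n_cases, " cases / ", spec$n_controls, " controls"),
        class = c("twasmeta_sampling_budget", "error", "condition")))
    nb <- min(batch, budget - drawn)
    d <- .sim_dosages(nb, cvar, architectures, ld_block_rho)
    drawn <- drawn + nb
    std <- sweep(.grex_raw(d, cvar, truth), 2, grex_sd, "/")
    lp <- intercept + as.vector(std %*% gammas[colnames(std)]) +
      spec$ancestry$pc_shift
    y <- rbinom(nb, 1L, plogis(lp))
    if (n_case < spec$n_cases) {
      take <- which(y == 1L)[seq_len(min(sum(y == 1L),
                                         spec$n_cases - n_case))]
      if (length(take)) {
        case_rows[[length(case_rows) + 1L]] <- d[take, , drop = FALSE]
        n_case <- n_case + length(take)
      }
    }
    if (n_ctrl < spec$n_controls) {
      take <- which(y == 0L)[seq_len(min(sum(y == 0L),
                                         spec$n_controls - n_ctrl))]
      if (length(take)) {
        ctrl_rows[[length(ctrl_rows) + 1L]] <- d[take, , drop = FALSE]
        n_ctrl <- n_ctrl + length(take)
      }
    }
  }
  dosage <- rbind(do.call(rbind, case_rows), do.call(rbind, ctrl_rows))
  rownames(dosage) <- sprintf("%s_%05d", spec$name, seq_len(nrow(dosage)))
  phenotype <- c(rep(1L, spec$n_cases), rep(0L, spec$n_controls))
  covariates <- data.frame(
    age = round(rnorm(nrow(dosage), 55, 8), 1),
    pc_surrogate = spec$ancestry$pc_shift + rnorm(nrow(dosage), 0, 0.25),
    row.names = rownames(dosage))
  structure(list(dosage = dosage, variants = cvar, phenotype = phenotype,
                 covariates = covariates, spec = spec, seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("Reference panel:", nrow(x$dosage), "samples,",
      ncol(x$dosage), "variants,", ncol(x$expression), "genes\n")
  invisible(x)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Cohort", x$spec$name, "(", x$spec$ancestry$label, "):",
      sum(x$phenotype == 1), "cases /", sum(x$phenotype == 0),
      "controls,", ncol(x$dosage), "variants\n")
  invisible(x)
}
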