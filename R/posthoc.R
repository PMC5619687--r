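# Multiple-testing control, QQ diagnostics, and enrichment of association
# among genes near known susceptibility loci.

#' Bonferroni per-test threshold
#'
#' @param m Number of tests (at least 1).
#' @param alpha Family-wise error level (default 0.05).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  stopifnot(m >= 1)
  alpha / m
}

#' Benjamini-Hochberg adjusted p-values against a full test count
#'
#' Step-up adjustment `q_i = min_{j >= i} p_(j) * m / j`, clipped at 1.
#' `m` may exceed the list length, supporting adjustment of a truncated
#' top-k list against the full genome-wide test count; this assumes the
#' unlisted p-values are all larger than the listed ones.
#'
#' @param p P-values in `(0, 1]`.
#' @param m Total number of tests, at least `length(p)`.
#' @return Adjusted values in the input order, monotone in the p-value
#'   ranks.
#' @export
bh_adjust <- function(p, m = length(p)) {
  stopifnot(all(p > 0 & p <= 1))
  if (m < length(p))
    stop("`m` must be at least the number of p-values supplied",
         call. = FALSE)
  p.adjust(p, method = "BH", n = m)
}

#' Classify genes as near or far from known susceptibility loci
#'
#' A gene is "near" a locus catalogue iff the minimum distance between its
#' gene-body interval `[start, end]` and any index-variant position on the
#' same chromosome is at most `window` (inclusive; overlap counts as
#' distance 0).
#'
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @param catalog data.frame with columns `locus_id`, `chrom`, `pos`
#'   (1-based index-variant positions).
#' @param window Base-pair window (default 250 kb).
#' @return Logical vector, `TRUE` for near genes, in `genes` row order.
#' @export
classify_proximity <- function(genes, catalog, window = 250000) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)),
            all(c("chrom", "pos") %in% names(catalog)),
            window >= 0, all(catalog$pos > 0))
  vapply(seq_len(nrow(genes)), function(i) {
    pos <- catalog$pos[catalog$chrom == genes$chrom[i]]
    if (!length(pos)) return(FALSE)
    d <- pmax(0, pmax(genes$start[i] - pos, pos - genes$end[i]))
    min(d) <= window
  }, logical(1))
}

#' Enrichment of significant genes near known loci
#'
#' Pearson chi-square on the 2x2 table of (near/far known loci) x
#' (significant/not), without continuity correction, one degree of
#' freedom, two-sided.
#'
#' @param a Near-locus significant count.
#' @param b Near-locus non-significant count.
#' @param c Far significant count.
#' @param d Far non-significant count.
#' @return List of class `enrichment_table`: the four counts, the near and
#'   far significant proportions, `chisq`, and `pvalue`.
#' @export
enrichment_chi2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(counts >= 0))
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    stop("both margins of the 2x2 table must be positive", call. = FALSE)
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(a = a, b = b, c = c, d = d,
                 prop_near = a / (a + b), prop_far = c / (c + d),
                 chisq = unname(ct$statistic),
                 pvalue = unname(ct$p.value)),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("Near known loci: %d/%d (%.1f%%); elsewhere: %d/%d (%.1f%%)\n",
              x$a, x$a + x$b, 100 * x$prop_near,
              x$c, x$c + x$d, 100 * x$prop_far))
  cat(sprintf("Chi-square = %.3f, p = %.3g\n", x$chisq, x$pvalue))
  invisible(x)
}

#' QQ plot coordinates on the -log10 scale
#'
#' Expected quantiles use the offset rule `-log10((i - 0.5) / n)` against
#' the sorted observed `-log10` p-values.
#'
#' @param p P-values in `(0, 1]`.
#' @return data.frame with columns `expected` and `observed`, sorted from
#'   least to most significant; same number of rows as `length(p)`.
#' @export
qq_points <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  n <- length(p)
  obs <- sort(-log10(p))
  data.frame(expected = sort(-log10((seq_len(n) - 0.5) / n)),
             observed = obs)
}
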