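#' Call SNPs from per-site base-count profiles
#'
#' Sites with coverage of `min_coverage` or below are excluded (the rule
#' is strictly "over" `min_coverage`). A kept site is a SNP when at least
#' two distinct bases each have a count strictly greater than
#' `maf` x coverage; the comparison is done on exact integer arithmetic
#' (`10 * count > 3 * coverage` for the default 0.3) so boundary counts
#' are never mis-rounded.
#'
#' @param profiles data.frame with `gene_id`, `site`, `sex`, `A`, `C`,
#'   `G`, `T`.
#' @param min_coverage coverage must be strictly greater than this
#'   (default 10).
#' @param maf allele-frequency threshold as a fraction of coverage
#'   (default 0.3, strict).
#' @return data.frame of kept sites with `coverage`, `n_alleles` (bases
#'   above the frequency threshold; never more than 3) and `is_snp`.
#' @export
call_snps <- function(profiles, min_coverage = 10, maf = 0.3) {
  check_columns(profiles, c("gene_id", "site", "sex", "A", "C", "G", "T"),
                "profiles")
  counts <- as.matrix(profiles[, c("A", "C", "G", "T")])
  if (any(counts < 0)) stop_field("base counts", "must be >= 0")
  coverage <- rowSums(counts)
  keep <- coverage > min_coverage
  counts <- counts[keep, , drop = FALSE]
  coverage <- coverage[keep]
  # exact rational comparison count/coverage > maf:
  # with maf = p/q in lowest terms, q*count > p*coverage
  fr <- as.integer(round(maf * 1e6))
  g <- gcd2(fr, 1e6L)
  p <- fr %/% g; q <- 1e6L %/% g
  above <- counts * q > outer(coverage * p, rep(1, 4))
  n_alleles <- rowSums(above)
  out <- profiles[keep, c("gene_id", "site", "sex")]
  out$coverage <- coverage
  out$n_alleles <- as.integer(n_alleles)
  out$is_snp <- n_alleles >= 2L
  rownames(out) <- NULL
  out
}

gcd2 <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Per-chromosome-class, per-sex gene SNP summary
#'
#' For each chromosome class and sex, the proportion of genes with at
#' least one SNP among genes with at least one site passing the coverage
#' filter (genes with no qualifying site are excluded from the
#' denominator), with an exact binomial confidence interval. Also reports
#' the per-gene SNP density (SNPs / qualifying sites).
#'
#' @param calls output of [call_snps()].
#' @param gene_classes data.frame mapping `gene_id` to `class` (e.g.
#'   `"autosome"` / `"Z"` or chromosome labels).
#' @return list with `summary` (per class x sex: `n_genes`,
#'   `n_genes_with_snp`, `proportion`, `ci_lower`, `ci_upper`) and
#'   `per_gene` (per gene x sex: `n_sites`, `n_snps`, `snp_density`).
#' @export
gene_snp_summary <- function(calls, gene_classes) {
  check_columns(calls, c("gene_id", "sex", "is_snp"), "calls")
  check_columns(gene_classes, c("gene_id", "class"), "gene_classes")
  per_gene <- do.call(rbind, lapply(
    split(calls, list(calls$gene_id, calls$sex), drop = TRUE),
    function(d) data.frame(gene_id = d$gene_id[1], sex = d$sex[1],
                           n_sites = nrow(d), n_snps = sum(d$is_snp),
                           stringsAsFactors = FALSE)))
  rownames(per_gene) <- NULL
  per_gene$snp_density <- per_gene$n_snps / per_gene$n_sites
  per_gene$class <- gene_classes$class[match(per_gene$gene_id,
                                             gene_classes$gene_id)]
  if (anyNA(per_gene$class))
    warning("some genes in `calls` have no class in `gene_classes`")
  groups <- split(per_gene, list(per_gene$class, per_gene$sex), drop = TRUE)
  summary <- do.call(rbind, lapply(groups, function(d) {
    n <- nrow(d); k <- sum(d$n_snps > 0)
    ci <- stats::binom.test(k, n)$conf.int
    data.frame(class = d$class[1], sex = d$sex[1], n_genes = n,
               n_genes_with_snp = k, proportion = k / n,
               ci_lower = ci[1], ci_upper = ci[2],
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(summary = summary, per_gene = per_gene)
}

#' Neutral Z/autosome diversity expectation from chromosome copy numbers
#'
#' In a female-heterogametic population with equal sex ratio there are
#' three Z copies for every four autosome copies per breeding pair
#' (1.5N versus 2N), so neutral diversity on the Z is expected at 0.75 of
#' the autosomal level.
#'
#' @param z_copies_per_pair,autosome_copies_per_pair chromosome copies per
#'   breeding pair (defaults 3 and 4).
#' @return the expected neutral Z/A diversity ratio (0.75 by default).
#' @export
neutral_za_expectation <- function(z_copies_per_pair = 3,
                                   autosome_copies_per_pair = 4) {
  if (z_copies_per_pair <= 0 || autosome_copies_per_pair <= 0)
    stop_field("copies per pair", "must be > 0")
  z_copies_per_pair / autosome_copies_per_pair
}

#' Z/autosome heterozygosity ratio with bootstrap interval
#'
#' Ratio of the mean per-gene SNP density on the Z to that on autosomes,
#' with a percentile bootstrap confidence interval over genes, compared
#' against the neutral copy-number expectation of
#' [neutral_za_expectation()] (0.75): when even the upper CI bound falls
#' below it, diversity on the Z is flagged as reduced below neutrality.
#'
#' @param per_gene data.frame with `gene_id`, `class` (`"Z"` /
#'   `"autosome"`) and `snp_density` (one sex at a time).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional seed.
#' @param neutral neutral reference ratio (default
#'   `neutral_za_expectation()`).
#' @param min_genes minimum genes per class (default 10).
#' @return list with `ratio`, `ci` (2-vector), `below_neutral`, `n_z`,
#'   `n_autosome`, `neutral`.
#' @export
het_ratio <- function(per_gene, n_boot = 1000, seed = NULL,
                      neutral = neutral_za_expectation(), min_genes = 10) {
  check_columns(per_gene, c("class", "snp_density"), "per_gene")
  z <- per_gene$snp_density[per_gene$class == "Z"]
  a <- per_gene$snp_density[per_gene$class == "autosome"]
  if (length(z) < min_genes || length(a) < min_genes)
    stop(sprintf("need at least %d genes per class", min_genes), call. = FALSE)
  if (mean(a) == 0) stop("zero autosomal SNP density", call. = FALSE)
  ratio <- mean(z) / mean(a)
  with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i) {
      zb <- mean(sample(z, replace = TRUE))
      ab <- mean(sample(a, replace = TRUE))
      if (ab == 0) NA_real_ else zb / ab
    }, numeric(1))
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    list(ratio = ratio, ci = ci, below_neutral = is.finite(ci[2]) &&
           ci[2] < neutral, n_z = length(z), n_autosome = length(a),
         neutral = neutral)
  })
}
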