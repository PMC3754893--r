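#' Per-gene lineage rate ratios
#'
#' Given per-gene divergence estimates for two species against the same
#' outgroup, forms the per-gene ratios K(sp1)/K(sp2) for Ka, Ks and omega.
#' Genes with an undefined or zero denominator are excluded and counted.
#'
#' @param est1,est2 data.frames as returned by [ng86_genewise()] for the
#'   (species1, outgroup) and (species2, outgroup) pairs; matched on
#'   `gene_id`.
#' @return data.frame with `gene_id`, `class`, `ratio_ka`, `ratio_ks`,
#'   `ratio_omega`; attribute `excluded` holds per-metric exclusion counts.
#' @export
lineage_rate_ratios <- function(est1, est2) {
  check_columns(est1, c("gene_id", "ka", "ks", "omega"), "est1")
  check_columns(est2, c("gene_id", "ka", "ks", "omega"), "est2")
  common <- intersect(est1$gene_id, est2$gene_id)
  if (length(common) < max(nrow(est1), nrow(est2)))
    warning("gene sets differ; restricting to their intersection")
  if (!length(common)) stop("no shared genes between the two estimates", call. = FALSE)
  a <- est1[match(common, est1$gene_id), ]
  b <- est2[match(common, est2$gene_id), ]
  ratio_of <- function(x, y) ifelse(!is.na(x) & !is.na(y) & y > 0, x / y, NA_real_)
  out <- data.frame(gene_id = common,
                    class = if ("class" %in% names(a)) a$class else NA_character_,
                    ratio_ka = ratio_of(a$ka, b$ka),
                    ratio_ks = ratio_of(a$ks, b$ks),
                    ratio_omega = ratio_of(a$omega, b$omega),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- c(ka = sum(is.na(out$ratio_ka)),
                             ks = sum(is.na(out$ratio_ks)),
                             omega = sum(is.na(out$ratio_omega)))
  out
}

#' Faster-Z rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum comparison of a per-gene
#' statistic (typically a lineage rate ratio) between Z-linked and
#' autosomal genes.
#'
#' @param values per-gene numeric values.
#' @param classes chromosome class per gene (`"Z"` / `"autosome"`).
#' @param min_genes minimum genes required per class (default 10).
#' @return list with `median_z`, `median_autosome`, `p_value`, `n_z`,
#'   `n_autosome`. If either class is empty the result carries
#'   `status = "no data"`; degenerate all-tied input gives p = 1.
#' @export
faster_z_test <- function(values, classes, min_genes = 10) {
  keep <- is.finite(values) & !is.na(classes)
  values <- values[keep]; classes <- classes[keep]
  z <- values[classes == "Z"]
  a <- values[classes == "autosome"]
  if (!length(z) || !length(a))
    return(list(status = "no data", median_z = median_or_na(z),
                median_autosome = median_or_na(a), p_value = NA_real_,
                n_z = length(z), n_autosome = length(a)))
  if (length(z) < min_genes || length(a) < min_genes)
    warning(sprintf("fewer than %d genes in a class; test may be unreliable",
                    min_genes))
  p <- if (length(unique(c(z, a))) == 1L) 1
       else suppressWarnings(stats::wilcox.test(z, a)$p.value)
  list(status = "ok", median_z = stats::median(z),
       median_autosome = stats::median(a),
       p_value = p, n_z = length(z), n_autosome = length(a))
}

# Z/autosome scaling of the per-generation mutation rate implied by a
# male:female mutation-rate ratio alpha: the Z spends 2/3 of its history in
# males, autosomes 1/2.
z_autosome_rate_scaling <- function(alpha) {
  ((2 * alpha + 1) / 3) / ((alpha + 1) / 2)
}

#' Male-driven evolution: estimate alpha from synonymous divergence
#'
#' The Z chromosome is transmitted through males two thirds of the time,
#' autosomes half of the time, so the ratio of synonymous (neutral)
#' divergence KsZ/KsA reflects the male:female mutation-rate ratio alpha:
#' alpha = (3 KsZ - 2 KsA) / (4 KsA - 3 KsZ).
#'
#' @param ks_z median synonymous divergence of Z-linked genes.
#' @param ks_a median synonymous divergence of autosomal genes.
#' @return object of class `alpha_estimate`: list with `ks_z`, `ks_a`,
#'   `ratio` (KsZ/KsA) and `alpha`.
#' @export
#' @examples
#' estimate_alpha(ks_z = 0.19, ks_a = 0.17)  # alpha ~ 2.09
estimate_alpha <- function(ks_z, ks_a) {
  if (!is.finite(ks_z) || ks_z <= 0) stop_field("ks_z", "must be > 0")
  if (!is.finite(ks_a) || ks_a <= 0) stop_field("ks_a", "must be > 0")
  denom <- 4 * ks_a - 3 * ks_z
  if (denom <= 0)
    stop("alpha undefined: KsZ/KsA at or above its saturation value of 4/3",
         call. = FALSE)
  structure(list(ks_z = ks_z, ks_a = ks_a, ratio = ks_z / ks_a,
                 alpha = (3 * ks_z - 2 * ks_a) / denom),
            class = "alpha_estimate")
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat(sprintf("alpha estimate: %.3f (KsZ = %.4f, KsA = %.4f, Z/A ratio = %.4f)\n",
              x$alpha, x$ks_z, x$ks_a, x$ratio))
  invisible(x)
}

#' Gametolog versus between-species synonymous divergence
#'
#' Compares synonymous divergence between Z-W gametolog pairs with the
#' synonymous divergence between two species. A gametolog median exceeding
#' the species median indicates that Z-W recombination stopped before the
#' species split.
#'
#' @param gametolog_ks numeric vector of Z-W gametolog Ks values.
#' @param species_ks numeric vector of between-species Ks values.
#' @return list with both medians, two-tailed rank-sum `p_value` (NA with
#'   `status = "insufficient data"` when either list has < 2 values), and
#'   logical `pre_speciation_suppression`.
#' @export
zw_vs_species_divergence_test <- function(gametolog_ks, species_ks) {
  if (any(gametolog_ks < 0, na.rm = TRUE) || any(species_ks < 0, na.rm = TRUE))
    stop("Ks values must be non-negative", call. = FALSE)
  g <- gametolog_ks[is.finite(gametolog_ks)]
  s <- species_ks[is.finite(species_ks)]
  if (!length(g) || !length(s)) stop("both Ks lists must be non-empty", call. = FALSE)
  med_g <- stats::median(g); med_s <- stats::median(s)
  if (length(g) < 2L || length(s) < 2L)
    return(list(status = "insufficient data", median_gametolog = med_g,
                median_species = med_s, p_value = NA_real_,
                pre_speciation_suppression = med_g > med_s))
  p <- if (length(unique(c(g, s))) == 1L) 1
       else suppressWarnings(stats::wilcox.test(g, s)$p.value)
  list(status = "ok", median_gametolog = med_g, median_species = med_s,
       p_value = p, pre_speciation_suppression = med_g > med_s)
}
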