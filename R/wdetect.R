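#' Detect female-biased (W-candidate) scaffolds with a Tukey fence
#'
#' The female proportion of coverage is computed from per-sex
#' median-normalized coverages (each sex divided by its autosomal median
#' coverage, so unequal library sizes cannot masquerade as female bias).
#' A scaffold is a W candidate when its female fraction exceeds
#' Q3 + `fence_k` x IQR of the autosomal female fractions.
#'
#' @param coverage data.frame with `scaffold_id`, `chrom`, `length`,
#'   `reads_f`, `reads_m`.
#' @param autosome_labels chromosome labels treated as autosomal (need
#'   >= 30 autosomal scaffolds for a stable fence).
#' @param fence_k Tukey fence multiplier (default 1.5).
#' @return data.frame of candidates: `id`, `source`, `reads_f`, `reads_m`,
#'   `female_fraction`, `evidence`; the fence and the autosomal quartiles
#'   are attached as attributes `fence`, `q3`, `iqr`.
#' @export
detect_female_biased_scaffolds <- function(coverage, autosome_labels,
                                           fence_k = 1.5) {
  check_columns(coverage, c("scaffold_id", "chrom", "length", "reads_f",
                            "reads_m"), "coverage")
  cov_f <- coverage$reads_f / coverage$length
  cov_m <- coverage$reads_m / coverage$length
  is_auto <- !is.na(coverage$chrom) & coverage$chrom %in% autosome_labels
  if (sum(is_auto) < 30)
    warning("fewer than 30 autosomal scaffolds: Tukey fence may be unstable")
  med_f <- median_or_na(cov_f[is_auto & cov_f > 0])
  med_m <- median_or_na(cov_m[is_auto & cov_m > 0])
  if (!is.finite(med_f) || !is.finite(med_m))
    stop("no autosomal scaffolds with nonzero coverage", call. = FALSE)
  nf <- cov_f / med_f
  nm <- cov_m / med_m
  frac <- ifelse(nf + nm > 0, nf / (nf + nm), NA_real_)
  qs <- stats::quantile(frac[is_auto], c(0.25, 0.75), na.rm = TRUE,
                        names = FALSE)
  iqr <- qs[2] - qs[1]
  if (iqr == 0) warning("degenerate autosomal IQR (= 0); fence equals Q3")
  fence <- qs[2] + fence_k * iqr
  hit <- !is.na(frac) & frac > fence
  out <- data.frame(id = coverage$scaffold_id[hit],
                    source = rep("genomic-scaffold", sum(hit)),
                    reads_f = coverage$reads_f[hit],
                    reads_m = coverage$reads_m[hit],
                    female_fraction = frac[hit],
                    evidence = rep(sprintf("female_fraction > Q3 + %.2g*IQR (%.4f)",
                                           fence_k, fence), sum(hit)),
                    stringsAsFactors = FALSE)
  attr(out, "fence") <- fence
  attr(out, "q3") <- qs[2]
  attr(out, "iqr") <- iqr
  out
}

#' Detect W-candidate gene scaffolds from mismatch-filtered read counts
#'
#' A scaffold is W-candidate when the female read count is strictly above
#' `min_reads_f` and the male read count strictly below `max_reads_m`
#' (counts are expected to come from mismatch-filtered alignments).
#'
#' @param counts data.frame with `id`, `reads_f`, `reads_m`.
#' @param min_reads_f female threshold (default 20, exclusive).
#' @param max_reads_m male threshold (default 2, exclusive).
#' @return data.frame of candidates in the [detect_female_biased_scaffolds()]
#'   layout with `source = "genomic-gene"`.
#' @export
detect_w_gene_scaffolds <- function(counts, min_reads_f = 20, max_reads_m = 2) {
  check_columns(counts, c("id", "reads_f", "reads_m"), "counts")
  hit <- counts$reads_f > min_reads_f & counts$reads_m < max_reads_m
  tot <- counts$reads_f + counts$reads_m
  data.frame(id = counts$id[hit], source = rep("genomic-gene", sum(hit)),
             reads_f = counts$reads_f[hit], reads_m = counts$reads_m[hit],
             female_fraction = ifelse(tot[hit] > 0,
                                      counts$reads_f[hit] / tot[hit], NA_real_),
             evidence = rep(sprintf("reads_f > %g & reads_m < %g",
                                    min_reads_f, max_reads_m), sum(hit)),
             stringsAsFactors = FALSE)
}

#' Detect W-candidate transcripts from expression plus genomic counts
#'
#' A transcript is W-candidate when its male/female genomic read-count
#' ratio is below `max_mf_ratio`, its female genomic read count above
#' `min_reads_f`, and its expression is female-specific (male FPKM equal
#' to 0 with female FPKM > 0). Transcripts with zero female reads have an
#' undefined ratio and are skipped with a reason.
#'
#' @param transcripts data.frame with `id`, `reads_f`, `reads_m`,
#'   `fpkm_f`, `fpkm_m`.
#' @param max_mf_ratio male/female genomic count ratio threshold
#'   (default 0.1, exclusive).
#' @param min_reads_f female genomic count threshold (default 30,
#'   exclusive).
#' @return data.frame of candidates (`source = "transcript"`); skipped
#'   transcripts are recorded in attribute `skipped`.
#' @export
detect_w_transcripts <- function(transcripts, max_mf_ratio = 0.1,
                                 min_reads_f = 30) {
  check_columns(transcripts, c("id", "reads_f", "reads_m", "fpkm_f", "fpkm_m"),
                "transcripts")
  undef <- transcripts$reads_f == 0
  t2 <- transcripts[!undef, , drop = FALSE]
  hit <- (t2$reads_m / t2$reads_f) < max_mf_ratio &
    t2$reads_f > min_reads_f & t2$fpkm_m == 0 & t2$fpkm_f > 0
  out <- data.frame(id = t2$id[hit], source = rep("transcript", sum(hit)),
                    reads_f = t2$reads_f[hit], reads_m = t2$reads_m[hit],
                    female_fraction = t2$reads_f[hit] /
                      (t2$reads_f[hit] + t2$reads_m[hit]),
                    evidence = rep(sprintf(
                      "m/f < %g & reads_f > %g & female-specific expression",
                      max_mf_ratio, min_reads_f), sum(hit)),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- data.frame(
    id = transcripts$id[undef],
    reason = rep("reads_f = 0: ratio undefined", sum(undef)),
    stringsAsFactors = FALSE)
  out
}

#' Mapping-stringency presets for W-candidate placement
#'
#' `default` keeps alignments with more than 150 aligned nucleotides;
#' `strict` requires at least 200 aligned nucleotides and identity above
#' 30%; `lenient` requires at least 100 aligned nucleotides.
#'
#' @param preset `"default"`, `"strict"` or `"lenient"`.
#' @return list with `min_aligned_nt` and `min_identity`.
#' @export
w_mapping_preset <- function(preset = c("default", "strict", "lenient")) {
  switch(match.arg(preset),
         default = list(min_aligned_nt = 150, min_identity = 0),
         strict = list(min_aligned_nt = 200, min_identity = 0.30),
         lenient = list(min_aligned_nt = 100, min_identity = 0))
}

#' Map W candidates to anchored chromosomes and test Z enrichment
#'
#' Keeps the best alignment per candidate (most aligned nucleotides, ties
#' broken by identity then id), filters by the mapping stringency, counts
#' candidates per target chromosome, and tests the proportion mapping to
#' the Z against its random expectation (`z_chromosome_fraction`, e.g. the
#' Z's share of the anchored genome) with a two-sided binomial test. The
#' fold excess is the observed Z proportion divided by the expectation.
#'
#' @param alignments data.frame with `candidate_id`, `target_chrom`,
#'   `target_position`, `aligned_nt`, `identity`.
#' @param z_chrom label of the Z chromosome.
#' @param z_chromosome_fraction expected share of candidates on the Z
#'   under random mapping.
#' @param min_aligned_nt,min_identity stringency (see
#'   [w_mapping_preset()]); `min_aligned_nt` is exclusive, matching the
#'   default "more than 150 nt" rule.
#' @return list with `mapped` (best hit per candidate after filtering),
#'   `per_chromosome` counts, `n_on_z`, `n_mapped`, `observed_fraction`,
#'   `fold_excess` and `p_value`; when nothing maps, `status = "no data"`.
#' @export
map_candidates_and_test_enrichment <- function(alignments, z_chrom = "chrZ",
                                               z_chromosome_fraction,
                                               min_aligned_nt = 150,
                                               min_identity = 0) {
  check_columns(alignments, c("candidate_id", "target_chrom", "aligned_nt",
                              "identity"), "alignments")
  if (!is.numeric(z_chromosome_fraction) || z_chromosome_fraction <= 0 ||
      z_chromosome_fraction >= 1)
    stop_field("z_chromosome_fraction", "must be in (0, 1)")
  ord <- order(alignments$candidate_id, -alignments$aligned_nt,
               -alignments$identity,
               as.character(alignments$target_chrom))
  best <- alignments[ord, , drop = FALSE]
  best <- best[!duplicated(best$candidate_id), , drop = FALSE]
  best <- best[best$aligned_nt > min_aligned_nt &
                 best$identity >= min_identity, , drop = FALSE]
  if (!nrow(best))
    return(list(status = "no data", mapped = best, n_mapped = 0L))
  n_on_z <- sum(best$target_chrom == z_chrom)
  n_mapped <- nrow(best)
  obs <- n_on_z / n_mapped
  list(status = "ok", mapped = best,
       per_chromosome = as.data.frame(table(chrom = best$target_chrom),
                                      stringsAsFactors = FALSE),
       n_on_z = n_on_z, n_mapped = n_mapped, observed_fraction = obs,
       fold_excess = obs / z_chromosome_fraction,
       p_value = stats::binom.test(n_on_z, n_mapped,
                                   z_chromosome_fraction)$p.value)
}
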