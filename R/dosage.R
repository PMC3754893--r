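add_log2_ratio <- function(records) {
  check_columns(records, c("gene_id", "chrom", "fpkm_f", "fpkm_m"), "records")
  if (any(records$fpkm_f < 0) || any(records$fpkm_m < 0))
    stop_field("fpkm", "must be >= 0")
  records$log2_ratio <- ifelse(records$fpkm_f > 0 & records$fpkm_m > 0,
                               log2(records$fpkm_f / records$fpkm_m),
                               NA_real_)
  records
}

#' Per-chromosome expression summary by sex, with Z-versus-autosome tests
#'
#' For each chromosome: the median FPKM per sex over genes expressed above
#' `cutoff` in that sex, and the median log2(F/M) ratio over genes above
#' `cutoff` in *both* sexes (a ratio needs both). Three rank-sum tests
#' compare the Z against all autosomes pooled: female levels, male levels,
#' and the F/M ratios. Run with `cutoffs = c(0, 1, 10)` to reproduce the
#' robustness analysis across expression filters.
#'
#' @param records expression data.frame (`gene_id`, `chrom`, `fpkm_f`,
#'   `fpkm_m`, optional `pos`).
#' @param z_chrom label of the Z chromosome.
#' @param cutoffs FPKM cutoff(s); genes must exceed the cutoff (strictly)
#'   to be kept. Default 0, i.e. all expressed genes.
#' @param min_genes minimum genes per chromosome after filtering
#'   (default 10), below which that chromosome is reported with
#'   `status = "no data"`.
#' @return data.frame with one row per chromosome x cutoff
#'   (`chrom`, `cutoff`, `n_ratio_genes`, `median_fpkm_f`,
#'   `median_fpkm_m`, `median_log2_ratio`, `status`), with the Z-vs-autosome
#'   test results attached as attribute `tests` (one row per cutoff:
#'   `p_female_level`, `p_male_level`, `p_ratio`).
#' @export
chromosome_expression_summary <- function(records, z_chrom = "chrZ",
                                          cutoffs = 0, min_genes = 10) {
  records <- add_log2_ratio(records)
  per_cut <- lapply(cutoffs, function(ct) {
    rows <- do.call(rbind, lapply(split(records, records$chrom), function(d) {
      f <- d$fpkm_f[d$fpkm_f > ct]
      m <- d$fpkm_m[d$fpkm_m > ct]
      both <- d$fpkm_f > ct & d$fpkm_m > ct
      r <- d$log2_ratio[both]
      data.frame(chrom = d$chrom[1], cutoff = ct,
                 n_ratio_genes = sum(both),
                 median_fpkm_f = median_or_na(f),
                 median_fpkm_m = median_or_na(m),
                 median_log2_ratio = median_or_na(r),
                 status = if (sum(both) < min_genes) "no data" else "ok",
                 stringsAsFactors = FALSE)
    }))
    rownames(rows) <- NULL

    is_z <- records$chrom == z_chrom
    both <- records$fpkm_f > ct & records$fpkm_m > ct
    wt <- function(x, y) {
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (!length(x) || !length(y)) return(NA_real_)
      if (length(unique(c(x, y))) == 1L) return(1)
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    }
    tests <- data.frame(
      cutoff = ct,
      p_female_level = wt(log2(records$fpkm_f[is_z & records$fpkm_f > ct]),
                          log2(records$fpkm_f[!is_z & records$fpkm_f > ct])),
      p_male_level = wt(log2(records$fpkm_m[is_z & records$fpkm_m > ct]),
                        log2(records$fpkm_m[!is_z & records$fpkm_m > ct])),
      p_ratio = wt(records$log2_ratio[is_z & both],
                   records$log2_ratio[!is_z & both]))
    list(rows = rows, tests = tests)
  })
  out <- do.call(rbind, lapply(per_cut, `[[`, "rows"))
  attr(out, "tests") <- do.call(rbind, lapply(per_cut, `[[`, "tests"))
  out
}

#' Fold expression difference implied by a median log2 ratio
#'
#' @param log2_ratio_median a finite median log2(F/M).
#' @return list with `fold` (= 2^|median|) and `direction`
#'   (`"reduction"` for negative input, `"increase"` for positive,
#'   `"none"` for 0).
#' @export
#' @examples
#' fold_change(-0.71)  # ~1.6-fold reduction
fold_change <- function(log2_ratio_median) {
  if (!is.finite(log2_ratio_median)) stop_field("log2_ratio_median", "must be finite")
  list(fold = 2^abs(log2_ratio_median),
       direction = if (log2_ratio_median < 0) "reduction"
                   else if (log2_ratio_median > 0) "increase" else "none")
}

#' Sliding-window median log2(F/M) profile along a chromosome
#'
#' Genes are ordered by position; a window of `window_genes` genes slides
#' one gene at a time, reporting the median log2 ratio and the median gene
#' position per window. Genes without a defined ratio are dropped first.
#'
#' @param records expression records for one chromosome, with `pos`.
#' @param window_genes window size in genes (default 30).
#' @return data.frame with `window_start_pos`, `window_center_pos`,
#'   `window_end_pos`, `median_log2_ratio`, `n_genes`.
#' @export
sliding_window_ratio <- function(records, window_genes = 30) {
  records <- add_log2_ratio(records)
  check_columns(records, "pos", "records")
  d <- records[is.finite(records$log2_ratio), , drop = FALSE]
  d <- d[order(d$pos), , drop = FALSE]
  n <- nrow(d)
  if (n < 1) stop("no genes with a defined ratio", call. = FALSE)
  w <- as.integer(window_genes)
  if (n < w) {
    warning(sprintf("only %d genes (< window of %d): single window", n, w))
    w <- n
  }
  starts <- seq_len(n - w + 1L)
  do.call(rbind, lapply(starts, function(i) {
    win <- d[i:(i + w - 1L), ]
    data.frame(window_start_pos = win$pos[1],
               window_center_pos = stats::median(win$pos),
               window_end_pos = win$pos[w],
               median_log2_ratio = stats::median(win$log2_ratio),
               n_genes = w)
  }))
}

#' Fraction of Z genes that are locally dosage-compensated
#'
#' Counts genes whose log2(F/M) ratio lies within `tolerance` of 0 among
#' genes with a defined ratio. Optionally tests whether the compensated
#' genes cluster along the chromosome with [nn_clustering_test()] against
#' the positions of all ratio-defined genes.
#'
#' @param records expression records (one chromosome, typically the Z).
#' @param tolerance half-width of the compensated band in log2 units
#'   (default 0.3, i.e. roughly 0.8 < F/M < 1.2).
#' @param cluster_test if `TRUE`, run the positional clustering test
#'   (requires `pos`).
#' @param n_perm,seed passed to [nn_clustering_test()].
#' @return list with `n_compensated`, `n_total`, `fraction`, and (when
#'   requested and feasible) `clustering`.
#' @export
#' @examples
#' # 80 of 431 genes inside +/-0.3 -> fraction 0.186
compensated_fraction <- function(records, tolerance = 0.3,
                                 cluster_test = FALSE, n_perm = 999,
                                 seed = NULL) {
  records <- add_log2_ratio(records)
  d <- records[is.finite(records$log2_ratio), , drop = FALSE]
  if (!nrow(d)) stop("no genes with a defined ratio", call. = FALSE)
  comp <- abs(d$log2_ratio) <= tolerance
  out <- list(n_compensated = sum(comp), n_total = nrow(d),
              fraction = mean(comp))
  if (cluster_test && "pos" %in% names(d) && sum(comp) >= 3)
    out$clustering <- nn_clustering_test(d$pos[comp], d$pos,
                                         n_perm = n_perm, seed = seed)
  out
}
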