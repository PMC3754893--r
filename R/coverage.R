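#' Normalize per-scaffold coverage by sex against the autosomal median
#'
#' Per-sex coverage is reads/length; each scaffold's per-sex coverage is
#' divided by the median coverage of autosomal scaffolds in that sex and
#' log2-transformed, so the autosomal median log2 coverage is exactly 0 in
#' each sex and hemizygous (Z-linked, degenerate-W) scaffolds are expected
#' at -1 in the female. Scaffolds with a zero count in a sex get `NA` (not
#' -Inf) for that sex and are excluded from the medians.
#'
#' @param coverage data.frame with `scaffold_id`, `chrom`, `length`,
#'   `reads_f`, `reads_m` (and optionally `start`).
#' @param autosome_labels chromosome labels to treat as autosomal.
#' @return data.frame with `scaffold_id`, `chrom`, `start` (if present),
#'   `log2_f`, `log2_m`, `log2_fm` (= log2_f - log2_m).
#' @export
normalize_coverage <- function(coverage, autosome_labels) {
  check_columns(coverage, c("scaffold_id", "chrom", "length", "reads_f",
                            "reads_m"), "coverage")
  if (any(coverage$length <= 0)) stop_field("length", "must be > 0")
  if (any(coverage$reads_f < 0) || any(coverage$reads_m < 0))
    stop_field("reads", "counts must be >= 0")
  cov_f <- ifelse(coverage$reads_f > 0, coverage$reads_f / coverage$length, NA)
  cov_m <- ifelse(coverage$reads_m > 0, coverage$reads_m / coverage$length, NA)
  is_auto <- !is.na(coverage$chrom) & coverage$chrom %in% autosome_labels
  med_f <- median_or_na(cov_f[is_auto])
  med_m <- median_or_na(cov_m[is_auto])
  if (!is.finite(med_f) || !is.finite(med_m))
    stop("no autosomal scaffold with nonzero counts in each sex", call. = FALSE)
  out <- data.frame(scaffold_id = coverage$scaffold_id, chrom = coverage$chrom,
                    stringsAsFactors = FALSE)
  if ("start" %in% names(coverage)) out$start <- coverage$start
  out$log2_f <- log2(cov_f / med_f)
  out$log2_m <- log2(cov_m / med_m)
  out$log2_fm <- out$log2_f - out$log2_m
  out
}

#' Classify chromosomes as autosomal or Z-linked from normalized coverage
#'
#' A chromosome is called Z-linked when its median female-minus-male log2
#' coverage falls below `z_threshold` (default -0.5, halfway between the
#' autosomal expectation of 0 and the hemizygous expectation of -1).
#' Scaffolds on a Z-called chromosome whose window-smoothed log2(F-M)
#' stays at or above `par_threshold` are flagged for pseudoautosomal-region
#' screening.
#'
#' @param normalized output of [normalize_coverage()].
#' @param z_threshold log2(F/M) call threshold (default -0.5).
#' @param par_threshold windowed log2(F/M) at or above which a scaffold on
#'   a Z chromosome is flagged as potential PAR (default -0.25).
#' @param min_scaffolds minimum scaffolds with data per chromosome
#'   (default 10); below it the call is `"insufficient data"`.
#' @param window_n smoothing window (scaffolds) for the PAR flag.
#' @return list with `chromosome_calls` (data.frame `chrom`, `n`,
#'   `median_log2_fm`, `call`) and `scaffold_flags` (data.frame
#'   `scaffold_id`, `chrom`, `smoothed_log2_fm`, `par_flag`).
#' @export
classify_linkage <- function(normalized, z_threshold = -0.5,
                             par_threshold = -0.25, min_scaffolds = 10,
                             window_n = 41) {
  check_columns(normalized, c("scaffold_id", "chrom", "log2_fm"), "normalized")
  keep <- !is.na(normalized$chrom) & is.finite(normalized$log2_fm)
  nn <- normalized[keep, , drop = FALSE]
  calls <- do.call(rbind, lapply(split(nn, nn$chrom), function(d) {
    med <- median_or_na(d$log2_fm)
    data.frame(chrom = d$chrom[1], n = nrow(d), median_log2_fm = med,
               call = if (nrow(d) < min_scaffolds) "insufficient data"
                      else if (med < z_threshold) "Z-linked" else "autosomal",
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL

  flags <- NULL
  z_chroms <- calls$chrom[calls$call == "Z-linked"]
  if (length(z_chroms)) {
    flags <- do.call(rbind, lapply(z_chroms, function(ch) {
      d <- nn[nn$chrom == ch, , drop = FALSE]
      sm <- if ("start" %in% names(d) && nrow(d) >= 2)
        smooth_along_chromosome(d$start, d$log2_fm, window_n = window_n)
      else d$log2_fm
      data.frame(scaffold_id = d$scaffold_id, chrom = ch,
                 smoothed_log2_fm = sm, par_flag = sm >= par_threshold,
                 stringsAsFactors = FALSE)
    }))
    rownames(flags) <- NULL
  }
  list(chromosome_calls = calls, scaffold_flags = flags)
}

#' Smooth a series of values along a chromosome
#'
#' Running-median (default) or smoothing-spline smoothing of values ordered
#' by position. Input need not be sorted; the result is returned in the
#' original input order, with the sort order recorded in the `"order"`
#' attribute.
#'
#' @param positions positions in bp.
#' @param values values to smooth (same length).
#' @param window_n running-median window in points (default 41; forced odd;
#'   1 = identity).
#' @param method `"runmed"` or `"spline"`.
#' @return numeric vector of smoothed values, aligned with the input.
#' @export
smooth_along_chromosome <- function(positions, values, window_n = 41,
                                    method = c("runmed", "spline")) {
  method <- match.arg(method)
  if (length(positions) != length(values))
    stop("`positions` and `values` must have equal length", call. = FALSE)
  if (length(values) < 2) stop("need at least 2 points", call. = FALSE)
  ord <- order(positions)
  v <- values[ord]
  sm <- if (method == "runmed") {
    k <- min(as.integer(window_n), length(v))
    if (k %% 2L == 0L) k <- k - 1L
    if (k <= 1L) v else as.numeric(stats::runmed(v, k, endrule = "median"))
  } else {
    ok <- is.finite(v)
    fit <- stats::smooth.spline(positions[ord][ok], v[ok])
    stats::predict(fit, positions[ord])$y
  }
  out <- numeric(length(v))
  out[ord] <- sm
  attr(out, "order") <- ord
  out
}
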