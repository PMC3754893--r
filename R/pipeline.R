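#' Configuration for the full analysis pipeline
#'
#' @param coverage,expression,pileup,hits data.frames or TSV paths for the
#'   respective inputs (any may be `NULL`; stages without inputs are
#'   skipped and logged).
#' @param w_alignments data.frame of W-candidate alignments for the
#'   enrichment test (see [map_candidates_and_test_enrichment()]), or `NULL`.
#' @param autosome_labels chromosome labels treated as autosomal.
#' @param z_chrom Z chromosome label.
#' @param z_chromosome_fraction expected Z share under random mapping.
#' @param z_threshold,par_threshold coverage-classification thresholds.
#' @param expression_cutoffs FPKM cutoffs for the dosage robustness sweep.
#' @param window_genes dosage sliding-window size.
#' @param tolerance compensated-gene band (log2).
#' @param n_perm Monte-Carlo permutations for clustering tests.
#' @param seed global seed; per-stage seeds are derived from it by fixed
#'   offsets.
#' @param out_dir if non-`NULL`, the report is also written there as JSON.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(coverage = NULL, expression = NULL, pileup = NULL,
                            hits = NULL, w_alignments = NULL,
                            autosome_labels = paste0("chr", 1:5),
                            z_chrom = "chrZ", z_chromosome_fraction = 0.076,
                            z_threshold = -0.5, par_threshold = -0.25,
                            expression_cutoffs = 0, window_genes = 30,
                            tolerance = 0.3, n_perm = 999, seed = 1L,
                            out_dir = NULL) {
  structure(list(coverage = coverage, expression = expression,
                 pileup = pileup, hits = hits, w_alignments = w_alignments,
                 autosome_labels = autosome_labels, z_chrom = z_chrom,
                 z_chromosome_fraction = z_chromosome_fraction,
                 z_threshold = z_threshold, par_threshold = par_threshold,
                 expression_cutoffs = expression_cutoffs,
                 window_genes = window_genes, tolerance = tolerance,
                 n_perm = n_perm, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

load_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the full ZW analysis pipeline
#'
#' Orchestrates anchoring, coverage-based sex-linkage classification,
#' W-candidate detection and enrichment, SNP/heterozygosity verification
#' and dosage statistics over whatever inputs the config provides. Stages
#' whose inputs are missing are skipped and recorded in the report, never
#' silently. The config (minus the data themselves) is echoed into the
#' report for provenance, and the report is deterministic under a fixed
#' seed.
#'
#' @param config a [pipeline_config()].
#' @return a report list with sections `config`, `skipped` and one entry
#'   per executed stage; written to `out_dir/report.json` when requested.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(schema_version = "1.0", skipped = character())
  echo <- config[setdiff(names(config),
                         c("coverage", "expression", "pileup", "hits",
                           "w_alignments", "out_dir"))]
  report$config <- echo

  coverage <- load_input(config$coverage, read_coverage_table)
  expression <- load_input(config$expression, read_expression_table)
  pileup <- load_input(config$pileup, read_pileup_table)
  hits <- load_input(config$hits, read_hits_table)

  skip <- function(stage, why) {
    message(sprintf("skipping stage '%s': %s", stage, why))
    report$skipped <<- c(report$skipped, sprintf("%s (%s)", stage, why))
  }

  if (!is.null(hits)) {
    report$anchoring <- assign_scaffolds(hits)
  } else skip("anchoring", "no homology hits provided")

  normalized <- NULL
  if (!is.null(coverage)) {
    normalized <- normalize_coverage(coverage, config$autosome_labels)
    cls <- classify_linkage(normalized, z_threshold = config$z_threshold,
                            par_threshold = config$par_threshold)
    report$sex_linkage <- list(chromosome_calls = cls$chromosome_calls,
                               n_par_flagged =
                                 if (is.null(cls$scaffold_flags)) 0L
                                 else sum(cls$scaffold_flags$par_flag))
    wc <- detect_female_biased_scaffolds(coverage, config$autosome_labels)
    report$w_detection <- list(n_candidates = nrow(wc),
                               fence = attr(wc, "fence"))
    if (!is.null(config$w_alignments)) {
      enr <- map_candidates_and_test_enrichment(
        config$w_alignments, z_chrom = config$z_chrom,
        z_chromosome_fraction = config$z_chromosome_fraction)
      report$w_enrichment <- enr[c("status", "n_on_z", "n_mapped",
                                   "observed_fraction", "fold_excess",
                                   "p_value")]
      if (enr$status == "ok" && "target_position" %in% names(enr$mapped)) {
        onz <- enr$mapped[enr$mapped$target_chrom == config$z_chrom, ]
        if (nrow(onz) >= 10)
          report$strata <- segment_strata(
            data.frame(z_position = onz$target_position,
                       identity = onz$identity))
      }
    }
  } else skip("coverage_sexing", "no coverage table provided")

  if (!is.null(pileup)) {
    calls <- call_snps(pileup)
    gene_classes <- if (!is.null(expression)) {
      ex <- add_log2_ratio(expression)
      data.frame(gene_id = ex$gene_id,
                 class = ifelse(ex$chrom == config$z_chrom, "Z", "autosome"))
    } else {
      data.frame(gene_id = unique(calls$gene_id), class = "autosome")
    }
    snp <- gene_snp_summary(calls, gene_classes)
    report$snp <- list(summary = snp$summary)
    per_sex <- split(snp$per_gene, snp$per_gene$sex)
    report$het_ratio <- lapply(per_sex, function(d) {
      res <- try(het_ratio(d, seed = derive_seed(config$seed, 7L)),
                 silent = TRUE)
      if (inherits(res, "try-error")) list(status = "no data") else res
    })
  } else skip("snp_het", "no pileup table provided")

  if (!is.null(expression)) {
    summ <- chromosome_expression_summary(expression,
                                          z_chrom = config$z_chrom,
                                          cutoffs = config$expression_cutoffs)
    z_rec <- expression[expression$chrom == config$z_chrom, , drop = FALSE]
    report$dosage <- list(summary = summ, tests = attr(summ, "tests"))
    zmed <- summ$median_log2_ratio[summ$chrom == config$z_chrom &
                                     summ$cutoff == config$expression_cutoffs[1]]
    if (length(zmed) && is.finite(zmed))
      report$dosage$z_fold <- fold_change(zmed)
    if (nrow(z_rec) >= 3) {
      report$dosage$compensated <- compensated_fraction(
        z_rec, tolerance = config$tolerance, cluster_test = TRUE,
        n_perm = config$n_perm, seed = derive_seed(config$seed, 11L))
      if (nrow(z_rec) >= config$window_genes)
        report$dosage$window_profile <-
          sliding_window_ratio(z_rec, window_genes = config$window_genes)
    }
  } else skip("dosage", "no expression table provided")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  report
}
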