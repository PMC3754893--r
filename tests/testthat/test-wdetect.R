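test_that("Tukey-fence detection flags female-specific scaffolds", {
  cov <- make_coverage(n_auto = 60, n_z = 0, exact = FALSE, seed = 2)
  w <- data.frame(scaffold_id = c("w1", "w2"), chrom = NA, start = NA,
                  length = 1e5, reads_f = c(5000, 5000),
                  reads_m = c(0, 4900), stringsAsFactors = FALSE)
  cands <- detect_female_biased_scaffolds(rbind(cov, w), autosomes)
  expect_true("w1" %in% cands$id)       # fraction 1.0
  expect_false("w2" %in% cands$id)      # fraction ~0.5
  expect_true(all(cands$female_fraction >= 0 & cands$female_fraction <= 1))
  # fence arithmetic: Q3 + 1.5 IQR of the autosomal fractions
  fr <- attr(cands, "q3") + 1.5 * attr(cands, "iqr")
  expect_equal(attr(cands, "fence"), fr)
})

test_that("fence detection is invariant to library-size imbalance", {
  cov <- make_coverage(n_auto = 60, n_z = 0, exact = FALSE, seed = 5)
  c1 <- detect_female_biased_scaffolds(cov, autosomes)
  cov2 <- transform(cov, reads_m = reads_m * 10)
  c2 <- detect_female_biased_scaffolds(cov2, autosomes)
  expect_equal(c1$id, c2$id)
})

test_that("null false-positive rate of the fence is at the Tukey level", {
  hits <- 0
  total <- 0
  for (s in 1:5) {
    cfg <- sim_config(seed = s, differentiated = FALSE,
                      n_autosomal_scaffolds = 400, n_z_scaffolds = 0,
                      n_w_scaffolds = 0)
    cov <- simulate_coverage(cfg)$coverage
    cands <- detect_female_biased_scaffolds(cov, autosomes)
    hits <- hits + nrow(cands)
    total <- total + nrow(cov)
  }
  expect_lt(hits / total, 0.03)
})

test_that("W-gene count rule is exactly the printed thresholds", {
  counts <- data.frame(id = c("a", "b", "c", "d"),
                       reads_f = c(25, 25, 15, 21),
                       reads_m = c(0, 2, 0, 1))
  got <- detect_w_gene_scaffolds(counts)
  expect_setequal(got$id, c("a", "d"))   # strict > 20 and < 2
})

test_that("W-transcript rule recovers planted transcripts with no false positives", {
  set.seed(31)
  n <- 10000
  tr <- data.frame(id = sprintf("t%05d", 1:n),
                   reads_f = rpois(n, 60), reads_m = rpois(n, 55),
                   fpkm_f = rlnorm(n, 1, 1), fpkm_m = rlnorm(n, 1, 1))
  planted <- sample(n, 12)
  tr$reads_f[planted] <- 80
  tr$reads_m[planted] <- 3
  tr$fpkm_f[planted] <- 10
  tr$fpkm_m[planted] <- 0
  got <- detect_w_transcripts(tr)
  expect_setequal(got$id, tr$id[planted])
  # boundary cases
  tr2 <- data.frame(id = c("ok", "ratio", "lowf", "expressed_m", "zerof"),
                    reads_f = c(40, 40, 25, 40, 0),
                    reads_m = c(1, 4, 1, 1, 0),
                    fpkm_f = c(10, 10, 10, 10, 10),
                    fpkm_m = c(0, 0, 0, 0.5, 0))
  got2 <- detect_w_transcripts(tr2)
  expect_equal(got2$id, "ok")
  expect_equal(attr(got2, "skipped")$id, "zerof")
})

test_that("detectors are monotone in their thresholds", {
  set.seed(9)
  counts <- data.frame(id = sprintf("s%03d", 1:200),
                       reads_f = rpois(200, 25), reads_m = rpois(200, 2))
  strict <- detect_w_gene_scaffolds(counts, min_reads_f = 25, max_reads_m = 1)
  lenient <- detect_w_gene_scaffolds(counts, min_reads_f = 15, max_reads_m = 3)
  expect_true(all(strict$id %in% lenient$id))
  tr <- data.frame(id = counts$id, reads_f = counts$reads_f * 2,
                   reads_m = counts$reads_m,
                   fpkm_f = rlnorm(200), fpkm_m = rbinom(200, 1, 0.5) * 2)
  t_strict <- detect_w_transcripts(tr, max_mf_ratio = 0.05, min_reads_f = 40)
  t_lenient <- detect_w_transcripts(tr, max_mf_ratio = 0.2, min_reads_f = 20)
  expect_true(all(t_strict$id %in% t_lenient$id))
})

test_that("Z-enrichment fold and binomial test follow the printed arithmetic", {
  # 49% of 100 mapped candidates on the Z vs a 7.6% size share: 6.4-fold
  aln <- data.frame(candidate_id = sprintf("c%03d", 1:100),
                    target_chrom = c(rep("chrZ", 49), rep("chr1", 51)),
                    target_position = 1e6, aligned_nt = 300, identity = 0.6)
  res <- map_candidates_and_test_enrichment(aln, "chrZ",
                                            z_chromosome_fraction = 0.076)
  expect_equal(res$fold_excess, 0.49 / 0.076, tolerance = 1e-12)
  expect_equal(round(res$fold_excess, 1), 6.4)
  expect_lt(res$p_value, 1e-15)
  # homomorphic pattern: observed ~ expected, fold ~ 0.86, not significant
  aln2 <- aln
  aln2$target_chrom <- c(rep("chrZ", 6), rep("chr1", 94))
  res2 <- map_candidates_and_test_enrichment(aln2, "chrZ", 0.07)
  expect_equal(res2$fold_excess, 6 / 100 / 0.07, tolerance = 1e-12)
  expect_gt(res2$p_value, 0.05)
  # observed equal to expected: fold exactly 1
  aln3 <- aln
  aln3$target_chrom <- c(rep("chrZ", 10), rep("chr2", 90))
  expect_equal(map_candidates_and_test_enrichment(aln3, "chrZ",
                                                  0.1)$fold_excess, 1)
})

test_that("mapping keeps the best alignment per candidate and applies stringency", {
  aln <- data.frame(candidate_id = c("c1", "c1", "c2", "c3"),
                    target_chrom = c("chrZ", "chr1", "chr2", "chrZ"),
                    target_position = 1, aligned_nt = c(400, 200, 150, 180),
                    identity = c(0.5, 0.9, 0.5, 0.2))
  res <- map_candidates_and_test_enrichment(aln, "chrZ", 0.076)
  # c1 -> best hit chrZ (400 nt); c2 dropped (150 not > 150); c3 kept
  expect_equal(sort(res$mapped$candidate_id), c("c1", "c3"))
  strict <- w_mapping_preset("strict")
  res2 <- map_candidates_and_test_enrichment(
    aln, "chrZ", 0.076, min_aligned_nt = strict$min_aligned_nt,
    min_identity = strict$min_identity)
  expect_equal(res2$mapped$candidate_id, "c1")
  none <- map_candidates_and_test_enrichment(aln[3, ], "chrZ", 0.076)
  expect_equal(none$status, "no data")
  expect_null(none$p_value)
})
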