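test_that("chromosome summary recovers the constructed Z deficit", {
  ex <- make_expression(n_auto = 200, n_z = 100, z_ratio = -1, noise = 0)
  summ <- chromosome_expression_summary(ex)
  expect_equal(summ$median_log2_ratio[summ$chrom == "chr1"], 0)
  expect_equal(summ$median_log2_ratio[summ$chrom == "chrZ"], -1)
  tests <- attr(summ, "tests")
  expect_lt(tests$p_ratio, 1e-10)
  expect_lt(tests$p_female_level, 0.05)
  # compensated Z: ratio ~ 0 everywhere, like a homomorphic genome
  ex0 <- make_expression(n_auto = 200, n_z = 100, z_ratio = 0, noise = 0.1)
  s0 <- chromosome_expression_summary(ex0)
  expect_equal(s0$median_log2_ratio[s0$chrom == "chrZ"], 0, tolerance = 0.05)
})

test_that("summary is order-invariant, scale-invariant and cutoff-robust", {
  ex <- make_expression(n_auto = 300, n_z = 150, z_ratio = -0.71,
                        noise = 0.4, seed = 9)
  s1 <- chromosome_expression_summary(ex)
  s2 <- chromosome_expression_summary(ex[sample(nrow(ex)), ])
  expect_equal(s1$median_log2_ratio, s2$median_log2_ratio)
  exs <- transform(ex, fpkm_f = fpkm_f * 3.7, fpkm_m = fpkm_m * 3.7)
  s3 <- chromosome_expression_summary(exs)
  expect_equal(s1$median_log2_ratio, s3$median_log2_ratio, tolerance = 1e-12)
  sweep <- chromosome_expression_summary(ex, cutoffs = c(0, 1, 10))
  zs <- sweep[sweep$chrom == "chrZ", ]
  expect_equal(nrow(zs), 3)
  expect_lt(max(zs$median_log2_ratio) - min(zs$median_log2_ratio), 0.2)
})

test_that("genes with a zero in either sex are excluded from ratio statistics", {
  ex <- make_expression(n_auto = 30, n_z = 15, z_ratio = -1, noise = 0)
  ex$fpkm_f[1] <- 0
  ex$fpkm_m[2] <- 0
  summ <- chromosome_expression_summary(ex)
  expect_equal(summ$n_ratio_genes[summ$chrom == "chr1"], 28)
  tiny <- chromosome_expression_summary(ex[ex$chrom == "chrZ", ][1:5, ],
                                        min_genes = 10)
  expect_equal(tiny$status, "no data")
})

test_that("fold change matches the printed conversions", {
  expect_equal(signif(fold_change(-0.71)$fold, 2), 1.6)
  expect_equal(fold_change(-0.71)$fold, 2^0.71)
  expect_equal(fold_change(-0.71)$direction, "reduction")
  expect_equal(fold_change(0)$fold, 1)
  expect_equal(fold_change(0)$direction, "none")
  expect_equal(fold_change(-1)$fold, 2)
  expect_equal(fold_change(0.5)$direction, "increase")
  expect_error(fold_change(NA), "finite")
})

test_that("sliding window equals the brute-force oracle and finds planted segments", {
  set.seed(14)
  n <- 180
  pos <- sort(runif(n, 0, 8e7))
  ratio <- rnorm(n, -1, 0.1)
  inside <- pos > 3e7 & pos < 5e7
  ratio[inside][seq_len(min(60, sum(inside)))] <- rnorm(
    min(60, sum(inside)), 0, 0.1)
  ex <- data.frame(gene_id = sprintf("g%03d", 1:n), chrom = "chrZ",
                   pos = pos, fpkm_f = 2^ratio, fpkm_m = 1)
  win <- sliding_window_ratio(ex, window_genes = 30)
  expect_equal(win$median_log2_ratio,
               oracle_window_medians(pos, ratio, 30), tolerance = 1e-10)
  expect_gt(max(win$median_log2_ratio[win$window_center_pos > 3e7 &
                                        win$window_center_pos < 5e7]), -0.3)
  # constant input gives a flat profile
  exc <- transform(ex, fpkm_f = 0.5, fpkm_m = 1)
  expect_true(all(sliding_window_ratio(exc, 30)$median_log2_ratio == -1))
  # window equal to the gene count collapses to the chromosome median
  whole <- sliding_window_ratio(ex, window_genes = n)
  expect_equal(nrow(whole), 1)
  expect_equal(whole$median_log2_ratio, median(ratio))
  expect_warning(sliding_window_ratio(ex[1:10, ], 30), "single window")
})

test_that("compensated fraction: printed counts, limits and monotonicity", {
  set.seed(2)
  r <- c(runif(80, -0.29, 0.29), runif(351, 0.31, 2) *
           sample(c(-1, 1), 351, replace = TRUE))
  ex <- data.frame(gene_id = sprintf("g%03d", seq_along(r)), chrom = "chrZ",
                   pos = runif(length(r), 0, 8e7), fpkm_f = 2^r, fpkm_m = 1)
  res <- compensated_fraction(ex, tolerance = 0.3)
  expect_equal(res$n_compensated, 80)
  expect_equal(res$n_total, 431)
  expect_equal(res$fraction, 80 / 431)
  expect_equal(round(res$fraction, 3), 0.186)
  # monotone in tolerance
  fr <- vapply(c(0, 0.1, 0.3, 0.5, 2), function(tol)
    compensated_fraction(ex, tolerance = tol)$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[1], 0)
  all0 <- transform(ex, fpkm_f = 1, fpkm_m = 1)
  expect_equal(compensated_fraction(all0, 0.3)$fraction, 1)
  # positional clustering hook
  res2 <- compensated_fraction(ex, tolerance = 0.3, cluster_test = TRUE,
                               n_perm = 199, seed = 1)
  expect_true(res2$clustering$p_value > 0 && res2$clustering$p_value <= 1)
})
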