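test_that("config validation names the offending field", {
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(z_length = -1), "z_length")
  expect_error(sim_config(w_mismap = 2), "w_mismap")
  expect_error(sim_config(buffering = 0.2), "buffering")
  expect_error(sim_config(compensated_frac = 1.5), "compensated_frac")
  bad <- data.frame(start = c(0, 1e7), end = c(2e7, 3e7),
                    w_survival_prob = 0.1, zw_identity = 0.5)
  expect_error(sim_config(strata = bad), "overlap")
  expect_warning(sim_config(strata = data.frame()[0, ]), "single stratum")
})

test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 99, n_autosomal_scaffolds = 50, n_z_scaffolds = 10)
  expect_identical(simulate_coverage(cfg), simulate_coverage(cfg))
  expect_identical(simulate_strata_w_content(cfg),
                   simulate_strata_w_content(cfg))
  expect_identical(simulate_expression(cfg, 50, 20),
                   simulate_expression(cfg, 50, 20))
  g <- data.frame(gene_id = c("a", "b"), class = c("Z", "autosome"))
  expect_identical(simulate_pileups(cfg, g, sites_per_gene = 30),
                   simulate_pileups(cfg, g, sites_per_gene = 30))
  s1 <- simulate_codon_alignments(cfg, 3, 20)
  s2 <- simulate_codon_alignments(cfg, 3, 20)
  expect_identical(s1$alignments[[1]]$seqs, s2$alignments[[1]]$seqs)
})

test_that("coverage generator produces the expected sex pattern", {
  cfg <- sim_config(seed = 5)
  sim <- simulate_coverage(cfg)
  cov <- sim$coverage
  expect_equal(nrow(cov), nrow(sim$truth))
  expect_false(anyDuplicated(sim$truth$scaffold_id) > 0)
  auto <- sim$truth$linkage_class == "autosome"
  z <- sim$truth$linkage_class == "Z"
  w <- sim$truth$linkage_class == "W"
  # symmetric construction on autosomes
  expect_equal(median(cov$reads_f[auto] / cov$reads_m[auto]), 1,
               tolerance = 0.03)
  # females carry one Z, half coverage
  expect_equal(median(cov$reads_f[z] / cov$reads_m[z]), 0.5,
               tolerance = 0.03)
  # W: half female depth, ~1% male leakage
  expect_equal(median(cov$reads_m[w] / cov$reads_f[w]), 0.02,
               tolerance = 0.5)
  # a boa-like genome has no W and no female Z deficit
  boa <- simulate_coverage(sim_config(seed = 5, differentiated = FALSE))
  expect_false(any(boa$truth$linkage_class == "W"))
  bz <- boa$truth$linkage_class == "Z"
  expect_equal(median(boa$coverage$reads_f[bz] / boa$coverage$reads_m[bz]),
               1, tolerance = 0.03)
})

test_that("W-content generator respects stratum survival and identity", {
  cfg <- sim_config(seed = 21)
  sim <- simulate_strata_w_content(cfg)
  cand <- sim$candidates
  # density ranks: middle stratum (survival 0.05) lowest
  dens <- sim$truth$n_survivors / sim$truth$n_slots
  expect_equal(which.min(dens), 2L)
  expect_equal(order(dens), order(sim$truth$w_survival_prob))
  # empirical survival within 3 binomial SEs of the configured one
  for (s in 1:3) {
    p <- sim$truth$w_survival_prob[s]
    n <- sim$truth$n_slots[s]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(dens[s] - p), 3 * se + 1e-9)
  }
  # zero survival -> zero candidates in that interval
  cfg0 <- sim_config(seed = 21)
  cfg0$strata$w_survival_prob[2] <- 0
  sim0 <- simulate_strata_w_content(cfg0)
  mid <- sim0$candidates$z_position >= cfg0$strata$start[2] &
    sim0$candidates$z_position < cfg0$strata$end[2]
  expect_equal(sum(mid), 0)
  # identity 1 -> W sequences byte-identical to Z
  cfg1 <- sim_config(seed = 4, z_length = 1e7,
                     strata = data.frame(start = 0, end = 1e7,
                                         w_survival_prob = 0.5,
                                         zw_identity = 1))
  sim1 <- simulate_strata_w_content(cfg1, sequences = TRUE, seq_length = 50)
  expect_identical(sim1$z_seq, sim1$w_seq)
})

test_that("codon generator honours its dials", {
  # Ka/Ks target 0 -> every taxon encodes the same protein
  cfg <- sim_config(seed = 2, omega_target = 0)
  sim <- simulate_codon_alignments(cfg, 5, 30)
  for (al in sim$alignments) {
    prots <- vapply(al$seqs, function(s)
      paste(seqinr::translate(strsplit(s, "")[[1]]), collapse = ""),
      character(1))
    expect_equal(length(unique(prots)), 1L)
  }
  expect_error(simulate_codon_alignments(cfg, 5, 5), "codons_per_gene")
  expect_error(simulate_codon_alignments(cfg, 0, 30), "n_genes")
  # alpha = 1: Z and autosomal Ks indistinguishable
  cfg1 <- sim_config(seed = 3, alpha_sim = 1)
  sim1 <- simulate_codon_alignments(cfg1, 200, 60)
  est <- ng86_genewise(sim1$alignments, "differentiated1", "differentiated2")
  p <- wilcox.test(est$ks[est$class == "Z"],
                   est$ks[est$class == "autosome"])$p.value
  expect_gt(p, 0.001)
})

test_that("expression generator hits its dose targets", {
  cfg <- sim_config(seed = 8, compensated_frac = 0)
  sim <- simulate_expression(cfg, n_auto = 400, n_z = 400)
  r <- log2(sim$expression$fpkm_f / sim$expression$fpkm_m)
  z <- sim$truth$class == "Z"
  expect_equal(median(r[!z]), 0, tolerance = 0.06)
  expect_equal(median(r[z]), -0.71, tolerance = 0.06)
  # full compensation restores parity
  cfg1 <- sim_config(seed = 8, compensated_frac = 1)
  sim1 <- simulate_expression(cfg1, n_auto = 50, n_z = 400)
  r1 <- log2(sim1$expression$fpkm_f / sim1$expression$fpkm_m)
  expect_equal(median(r1[sim1$truth$class == "Z"]), 0, tolerance = 0.06)
  # buffering dial moves the target: full -1 dose
  cfg2 <- sim_config(seed = 8, buffering = 1, compensated_frac = 0)
  sim2 <- simulate_expression(cfg2, n_auto = 50, n_z = 400)
  r2 <- log2(sim2$expression$fpkm_f / sim2$expression$fpkm_m)
  expect_equal(median(r2[sim2$truth$class == "Z"]), -1, tolerance = 0.06)
})

test_that("pileup generator encodes hemizygosity and theta", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:30),
                      class = rep(c("autosome", "Z"), 15))
  cfg <- sim_config(seed = 13, theta = list(autosome = c(f = 0.02, m = 0.02),
                                            z = c(f = 0, m = 0.02)))
  pile <- simulate_pileups(cfg, genes, sites_per_gene = 150)
  calls <- call_snps(pile)
  summ <- gene_snp_summary(calls, genes)$summary
  fz <- summ[summ$class == "Z" & summ$sex == "f", ]
  mz <- summ[summ$class == "Z" & summ$sex == "m", ]
  expect_equal(fz$proportion, 0)
  expect_gt(mz$proportion, 0.5)
  fa <- summ[summ$class == "autosome" & summ$sex == "f", ]
  ma <- summ[summ$class == "autosome" & summ$sex == "m", ]
  # same theta in both sexes: proportions within joint binomial error
  expect_lt(abs(fa$proportion - ma$proportion),
            3 * sqrt(0.5 / fa$n_genes) + 1e-9)
  # theta 0 everywhere -> no SNPs at all
  cfg0 <- sim_config(seed = 13, theta = list(autosome = c(f = 0, m = 0),
                                             z = c(f = 0, m = 0)))
  pile0 <- simulate_pileups(cfg0, genes, sites_per_gene = 60,
                            error_rate = 0)
  expect_equal(sum(call_snps(pile0)$is_snp), 0)
})
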