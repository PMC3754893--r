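test_that("nearest-neighbour test flags strong clustering, never returns 0", {
  universe <- seq(0, 8e7, by = 4e4)
  clustered <- runif(30, 0, 8e5)   # all within 1% of the chromosome
  res <- nn_clustering_test(clustered, universe, n_perm = 2000, seed = 1)
  expect_lte(res$p_value, 0.001)
  expect_gt(res$p_value, 0)
  expect_lt(res$observed_mean_nn, res$null_mean)
  # add-one correction bounds the p away from 0 at any n_perm
  res2 <- nn_clustering_test(clustered, universe, n_perm = 9, seed = 1)
  expect_gte(res2$p_value, 1 / 10)
})

test_that("nearest-neighbour test error contracts", {
  universe <- 1:100
  expect_error(nn_clustering_test(c(1, 2), universe), "insufficient")
  expect_error(nn_clustering_test(c(1, 2, 3), universe, n_perm = 0), "n_perm")
  expect_error(nn_clustering_test(1:50, 1:10), "universe")
})

test_that("uniform density yields one segment; planted regimes are recovered", {
  set.seed(8)
  uni <- data.frame(z_position = runif(300, 0, 8e7))
  seg <- segment_strata(uni, method = "changepoint", z_length = 8e7)
  expect_equal(nrow(seg), 1)
  cfg <- sim_config(seed = 12)
  sim <- simulate_strata_w_content(cfg)
  seg3 <- segment_strata(sim$candidates, method = "changepoint",
                         z_length = 8e7)
  expect_equal(nrow(seg3), 3)
  expect_lt(abs(seg3$end[1] - 2e7), 3e6)
  expect_lt(abs(seg3$end[2] - 5e7), 3e6)
  expect_equal(which.min(seg3$density_per_mb), 2L)
})

test_that("fixed-boundary mode conserves counts and ranks the middle lowest", {
  cfg <- sim_config(seed = 23)
  sim <- simulate_strata_w_content(cfg)
  seg <- segment_strata(sim$candidates, method = "fixed", z_length = 8e7,
                        boundaries = c(0, 2e7, 5e7, 8e7))
  expect_equal(sum(seg$n_candidates), nrow(sim$candidates))
  expect_equal(which.min(seg$density_per_mb), 2L)
  expect_equal(which.min(seg$median_identity), 2L)
  expect_equal(seg$label, c("younger", "older", "younger"))
  expect_error(segment_strata(sim$candidates, method = "fixed",
                              z_length = 8e7, boundaries = c(0, 9e7)),
               "outside")
})

test_that("identities below the low-quality threshold are excluded from medians", {
  mapped <- data.frame(z_position = seq(1e6, 2e7, by = 1e6),
                       identity = c(rep(0.1, 10), rep(0.6, 10)))
  seg <- segment_strata(mapped, method = "fixed", z_length = 8e7,
                        boundaries = c(0, 8e7))
  expect_equal(seg$median_identity, 0.6)
  seg2 <- segment_strata(mapped, method = "fixed", z_length = 8e7,
                         boundaries = c(0, 8e7), min_identity = 0)
  expect_equal(seg2$median_identity, 0.35)
})

test_that("cross-species overlap: identical, disjoint and null behaviour", {
  universe <- seq(0, 8e7, by = 1e5)
  set.seed(5)
  a <- sample(universe, 40)
  res <- cross_species_overlap_test(a, a, window_bp = 1e4,
                                    universe = universe, n_perm = 999,
                                    seed = 2)
  expect_equal(res$observed_overlap, 40)
  expect_lte(res$p_value, 0.01)
  left <- runif(20, 0, 3e7)
  right <- runif(20, 5e7, 8e7)
  res2 <- cross_species_overlap_test(left, right, window_bp = 1e6,
                                     universe = universe, n_perm = 99,
                                     seed = 3)
  expect_equal(res2$observed_overlap, 0)
  expect_equal(cross_species_overlap_test(numeric(0), a, 1e4,
                                          universe)$status, "no data")
})

test_that("shared-gene expectation follows the product formula", {
  res <- shared_gene_expectation(10, 20, 100, observed_shared = 2)
  expect_equal(res$expected, 2)
  expect_equal(res$chi_square, 0)
  expect_equal(res$p_value, 1)
  # printed W-gene counts with their printed denominator
  res2 <- shared_gene_expectation(55, 29, 712, observed_shared = 15)
  expect_equal(res2$expected, 55 * 29 / 712)
  expect_equal(res2$expected, 2.2402, tolerance = 1e-4)
  expect_lt(res2$p_value, 0.001)
  expect_error(shared_gene_expectation(10, 20, 0, 1), "n_total")
  expect_error(shared_gene_expectation(10, 20, 100, 15), "observed_shared")
})

test_that("topology verdicts follow the four-point structure", {
  set.seed(6)
  base <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  mutate <- function(s, d) {
    i <- sample(400, round(d * 400))
    s[i] <- vapply(s[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                            1), character(1))
    s
  }
  # W1/W2 close to each other, far from the Zs: clusters by chromosome
  w_anc <- mutate(base, 0.15)
  seqs <- c(z_sp1 = paste(mutate(base, 0.03), collapse = ""),
            z_sp2 = paste(mutate(base, 0.03), collapse = ""),
            w_sp1 = paste(mutate(w_anc, 0.03), collapse = ""),
            w_sp2 = paste(mutate(w_anc, 0.03), collapse = ""))
  chrom <- c(z_sp1 = "Z", z_sp2 = "Z", w_sp1 = "W", w_sp2 = "W")
  sp <- c(z_sp1 = "sp1", z_sp2 = "sp2", w_sp1 = "sp1", w_sp2 = "sp2")
  res <- gametolog_topology_test(seqs, chrom, species = sp)
  expect_equal(res$verdict, "clusters-by-chromosome")
  expect_match(res$newick, "w_sp1")
  # within-species pairs closest: clusters by species
  sp1_anc <- mutate(base, 0.15)
  seqs2 <- c(z_sp1 = paste(mutate(sp1_anc, 0.02), collapse = ""),
             w_sp1 = paste(mutate(sp1_anc, 0.02), collapse = ""),
             z_sp2 = paste(mutate(base, 0.02), collapse = ""),
             w_sp2 = paste(mutate(base, 0.02), collapse = ""))
  res2 <- gametolog_topology_test(seqs2, chrom, species = sp)
  expect_equal(res2$verdict, "clusters-by-species")
  # verdict invariant to input order and species relabeling
  perm <- c("w_sp2", "z_sp1", "w_sp1", "z_sp2")
  res3 <- gametolog_topology_test(seqs[perm], chrom, species = sp)
  expect_equal(res3$verdict, "clusters-by-chromosome")
  sp_swap <- c(z_sp1 = "sp2", z_sp2 = "sp1", w_sp1 = "sp2", w_sp2 = "sp1")
  res4 <- gametolog_topology_test(seqs, chrom, species = sp_swap)
  expect_equal(res4$verdict, "clusters-by-chromosome")
})

test_that("topology test guards short or saturated alignments", {
  seqs <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAA",
            d = "ACGTACGTAG")
  chrom <- c(a = "Z", b = "Z", c = "W", d = "W")
  expect_warning(res <- gametolog_topology_test(seqs, chrom),
                 "unresolved")
  expect_equal(res$verdict, "unresolved")
  expect_error(gametolog_topology_test(seqs[1:3], chrom), "at least 4")
})
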