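# small in-code fixtures shared across tests

make_coverage <- function(n_auto = 51, n_z = 11, depth = 100, len = 1e5,
                          exact = TRUE, seed = 1) {
  n <- n_auto + n_z
  base <- depth * len / 1000
  if (exact) {
    reads <- rep(base, n)
    reads_f <- reads
    reads_f[(n_auto + 1):n] <- base / 2
    reads_m <- reads
  } else {
    set.seed(seed)
    reads_f <- rpois(n, base * c(rep(1, n_auto), rep(0.5, n_z)))
    reads_m <- rpois(n, base)
  }
  data.frame(scaffold_id = sprintf("s%03d", 1:n),
             chrom = c(paste0("chr", 1 + (seq_len(n_auto) - 1) %% 5),
                       rep("chrZ", n_z)),
             start = seq(0, by = 2e5, length.out = n),
             length = len, reads_f = reads_f, reads_m = reads_m,
             stringsAsFactors = FALSE)
}

make_expression <- function(n_auto = 40, n_z = 20, z_ratio = -1, noise = 0,
                            seed = 1) {
  set.seed(seed)
  n <- n_auto + n_z
  m <- rlnorm(n, 2, 1)
  delta <- c(rep(0, n_auto), rep(z_ratio, n_z)) + rnorm(n, 0, noise)
  data.frame(gene_id = sprintf("g%03d", 1:n),
             chrom = c(rep("chr1", n_auto), rep("chrZ", n_z)),
             pos = round(runif(n, 0, 8e7)),
             fpkm_f = m * 2^delta, fpkm_m = m,
             stringsAsFactors = FALSE)
}

autosomes <- paste0("chr", 1:5)
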