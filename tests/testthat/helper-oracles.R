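# Independent brute-force oracles. These re-derive expectations from first
# principles, without the package's lookup tables, so they can vouch for the
# fast implementations.

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

oracle_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# synonymous site count of one codon; changes producing stops count as
# nonsynonymous
oracle_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa0 <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), ch[pos])) {
      alt <- ch
      alt[pos] <- b
      if (oracle_translate(paste(alt, collapse = "")) == aa0) s <- s + 1 / 3
    }
  }
  s
}

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in oracle_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

# pathway-averaged (Sd, Nd) between two codons; pathways via stop codons are
# dropped (all kept if none survives, stop steps then counted nonsynonymous)
oracle_pair_diffs <- function(c1, c2) {
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  diffs <- which(ch1 != ch2)
  if (!length(diffs)) return(c(sd = 0, nd = 0))
  paths <- oracle_perms(diffs)
  res <- lapply(paths, function(ord) {
    cur <- ch1
    sd <- 0; nd <- 0; valid <- TRUE
    for (k in seq_along(ord)) {
      nxt <- cur
      nxt[ord[k]] <- ch2[ord[k]]
      a1 <- oracle_translate(paste(cur, collapse = ""))
      a2 <- oracle_translate(paste(nxt, collapse = ""))
      if (a2 == "*" && k < length(ord)) valid <- FALSE
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, valid = valid)
  })
  ok <- vapply(res, `[[`, logical(1), "valid")
  if (!any(ok)) ok <- rep(TRUE, length(res))
  c(sd = mean(vapply(res[ok], `[[`, numeric(1), "sd")),
    nd = mean(vapply(res[ok], `[[`, numeric(1), "nd")))
}

oracle_ng86 <- function(seq1, seq2) {
  cods1 <- oracle_codons(seq1)
  cods2 <- oracle_codons(seq2)
  S <- (sum(vapply(cods1, oracle_syn_sites, numeric(1))) +
        sum(vapply(cods2, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(cods1) - S
  d <- rowSums(vapply(seq_along(cods1),
                      function(i) oracle_pair_diffs(cods1[i], cods2[i]),
                      numeric(2)))
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  # a class with zero sites necessarily has zero differences: report 0
  list(s_sites = S, n_sites = N, sd_obs = d[["sd"]], nd_obs = d[["nd"]],
       ks = jc(if (S > 0) d[["sd"]] / S else 0),
       ka = jc(if (N > 0) d[["nd"]] / N else 0))
}

# plain re-statement of the SNP rule for exhaustive comparison
oracle_snp_call <- function(a, c, g, t, min_coverage = 10) {
  cov <- a + c + g + t
  if (cov <= min_coverage) return(NA)
  sum(c(a, c, g, t) * 10 > 3 * cov) >= 2
}

# brute-force sliding-window medians over genes ordered by position
oracle_window_medians <- function(pos, ratio, w) {
  ord <- order(pos)
  r <- ratio[ord]
  vapply(seq_len(length(r) - w + 1L),
         function(i) median(r[i:(i + w - 1L)]), numeric(1))
}

# brute-force running median with edge copying (window k odd)
oracle_running_median <- function(v, k) {
  h <- (k - 1) / 2
  n <- length(v)
  out <- v
  for (i in (h + 1):(n - h)) out[i] <- median(v[(i - h):(i + h)])
  out
}
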