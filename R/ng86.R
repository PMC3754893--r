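#' Codon alignments
#'
#' A `codon_alignment` holds equal-length, in-frame aligned coding sequences
#' for one gene, keyed by taxon, plus the chromosome class the gene belongs
#' to (`"autosome"` or `"Z"`). Stop codons are rejected; gap (`-`) and
#' ambiguous (`N`) positions are allowed and are dropped codon-wise by
#' pairwise estimators.
#'
#' @param seqs named character vector of aligned nucleotide sequences
#'   (A/C/G/T plus `-`/`N`), one per taxon.
#' @param gene_id gene identifier.
#' @param class chromosome class, `"autosome"` or `"Z"`.
#' @return an object of class `codon_alignment` with elements `gene_id`,
#'   `class`, `seqs` and `n_codons`.
#' @export
codon_alignment <- function(seqs, gene_id = "gene", class = "autosome") {
  if (!is.character(seqs) || !length(seqs))
    stop("`seqs` must be a non-empty named character vector", call. = FALSE)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named by taxon", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon name in alignment", call. = FALSE)
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal length", call. = FALSE)
  if (lens[1] %% 3L != 0L)
    stop("alignment length not divisible by 3", call. = FALSE)
  if (lens[1] < 3L)
    stop("alignment must contain at least one codon", call. = FALSE)
  tab <- ng86_tables()
  for (i in seq_along(seqs)) {
    idx <- codon_indices(seqs[[i]])
    if (any(!is.na(idx) & tab$aa[idx] == "*"))
      stop(sprintf("sequence '%s' contains a stop codon", names(seqs)[i]),
           call. = FALSE)
  }
  structure(list(gene_id = gene_id, class = match.arg(class, c("autosome", "Z")),
                 seqs = seqs, n_codons = unname(lens[1]) %/% 3L),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment '%s' (%s): %d taxa x %d codons\n",
              x$gene_id, x$class, length(x$seqs), x$n_codons))
  invisible(x)
}

# codon string -> integer index 1..64 (NA for codons containing gaps/N);
# base order T,C,A,G as in the classic codon table
codon_indices <- function(seq) {
  tab <- ng86_tables()
  n <- nchar(seq) %/% 3L
  cods <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  match(cods, tab$codons)
}

# Lazily built NG86 lookup tables:
#   codons: the 64 codons; aa: amino acid per codon ('*' = stop);
#   syn_sites: synonymous site count per codon (changes to stops count as
#     nonsynonymous); SD/ND: pathway-averaged synonymous / nonsynonymous
#     difference counts per ordered codon pair (stop-codon pathways excluded,
#     weights renormalised); NDIFF: raw nucleotide differences per pair.
ng86_tables <- function() {
  if (!is.null(.zw_cache$ng86)) return(.zw_cache$ng86)
  bases <- c("T", "C", "A", "G")
  grid <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$b1, grid$b2, grid$b3)
  aa <- vapply(codons, function(cd)
    seqinr::translate(strsplit(cd, "")[[1]]), character(1))

  idx_of <- function(cd) match(cd, codons)
  neighbours <- function(cd, pos) {
    ch <- strsplit(cd, "")[[1]]
    out <- character(0)
    for (b in setdiff(bases, ch[pos])) {
      alt <- ch; alt[pos] <- b
      out <- c(out, paste(alt, collapse = ""))
    }
    out
  }

  syn_sites <- rep(NA_real_, 64L)
  for (i in seq_len(64L)) {
    if (aa[i] == "*") next
    s <- 0
    for (pos in 1:3) {
      alt <- neighbours(codons[i], pos)
      s <- s + sum(aa[idx_of(alt)] == aa[i]) / 3
    }
    syn_sites[i] <- s
  }

  perms <- list(`1` = list(1L), `2` = list(1:2, 2:1),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

  # classify one mutational pathway c1 -> c2 applying the differing positions
  # in the given order; returns c(sd, nd, valid) where valid = 0 if an
  # intermediate codon is a stop
  walk_path <- function(ch1, ch2, order_pos) {
    cur <- ch1
    sd <- 0; nd <- 0; valid <- 1
    for (k in seq_along(order_pos)) {
      nxt <- cur; p <- order_pos[k]; nxt[p] <- ch2[p]
      a1 <- aa[idx_of(paste(cur, collapse = ""))]
      a2 <- aa[idx_of(paste(nxt, collapse = ""))]
      if (a2 == "*" && k < length(order_pos)) valid <- 0
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, valid)
  }

  SD <- matrix(0, 64L, 64L)
  ND <- matrix(0, 64L, 64L)
  NDIFF <- matrix(0L, 64L, 64L)
  split_chars <- strsplit(codons, "")
  for (i in seq_len(64L)) {
    if (aa[i] == "*") next
    for (j in seq_len(64L)) {
      if (aa[j] == "*" || i == j) next
      ch1 <- split_chars[[i]]; ch2 <- split_chars[[j]]
      diffs <- which(ch1 != ch2)
      NDIFF[i, j] <- length(diffs)
      res <- vapply(perms[[as.character(length(diffs))]],
                    function(ord) walk_path(ch1, ch2, diffs[ord]),
                    numeric(3))
      ok <- res[3, ] > 0
      if (!any(ok)) ok <- rep(TRUE, ncol(res))  # all paths hit stops: keep all
      SD[i, j] <- mean(res[1, ok])
      ND[i, j] <- mean(res[2, ok])
    }
  }
  .zw_cache$ng86 <- list(codons = codons, aa = aa, syn_sites = syn_sites,
                         SD = SD, ND = ND, NDIFF = NDIFF)
  .zw_cache$ng86
}

# Jukes-Cantor multiple-hit correction of a raw proportion of differences
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise Ka/Ks with the Nei-Gojobori (1986) method
#'
#' Counts synonymous (S) and nonsynonymous (N) sites by codon-degeneracy
#' fractions averaged over the two sequences, classifies observed
#' differences by equal-weight averaging over all shortest mutational
#' pathways (pathways through stop codons excluded), and corrects the
#' proportions pS = Sd/S and pN = Nd/N for multiple hits with the
#' Jukes-Cantor formula d = -(3/4) log(1 - 4p/3). Codon columns containing
#' a gap or `N` in either sequence are dropped and counted.
#'
#' @param alignment a [codon_alignment()].
#' @param taxon_a,taxon_b taxa to compare (must be present in `alignment`).
#' @return one-row data.frame with columns `gene_id`, `class`, `taxon_a`,
#'   `taxon_b`, `ka`, `ks`, `omega` (NA when Ks = 0 or saturated), `s_sites`,
#'   `n_sites`, `sd_obs`, `nd_obs`, `codons_used`, `codons_dropped`,
#'   `ka_saturated`, `ks_saturated`. A saturated proportion (p >= 3/4)
#'   yields NA for the corresponding rate.
#' @export
#' @examples
#' aln <- codon_alignment(c(a = "TTT", b = "TTA"))
#' ng86_pairwise(aln, "a", "b")  # Ka ~ 0.5716, Ks = 0
ng86_pairwise <- function(alignment, taxon_a, taxon_b) {
  stopifnot(inherits(alignment, "codon_alignment"))
  for (tx in c(taxon_a, taxon_b))
    if (!tx %in% names(alignment$seqs))
      stop(sprintf("taxon '%s' not present in alignment", tx), call. = FALSE)
  tab <- ng86_tables()
  c1 <- codon_indices(alignment$seqs[[taxon_a]])
  c2 <- codon_indices(alignment$seqs[[taxon_b]])
  keep <- !is.na(c1) & !is.na(c2)
  dropped <- sum(!keep)
  c1 <- c1[keep]; c2 <- c2[keep]
  if (!length(c1))
    stop("no gap-free codon columns shared by the two taxa", call. = FALSE)

  S <- (sum(tab$syn_sites[c1]) + sum(tab$syn_sites[c2])) / 2
  N <- 3 * length(c1) - S
  Sd <- sum(tab$SD[cbind(c1, c2)])
  Nd <- sum(tab$ND[cbind(c1, c2)])

  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  ks <- jc_correct(pS)
  ka <- jc_correct(pN)
  data.frame(gene_id = alignment$gene_id, class = alignment$class,
             taxon_a = taxon_a, taxon_b = taxon_b,
             ka = ka, ks = ks,
             omega = if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_,
             s_sites = S, n_sites = N, sd_obs = Sd, nd_obs = Nd,
             codons_used = length(c1), codons_dropped = dropped,
             ka_saturated = is.na(ka), ks_saturated = is.na(ks),
             stringsAsFactors = FALSE)
}

#' Apply [ng86_pairwise()] to a list of alignments
#'
#' @param alignments list of [codon_alignment()] objects.
#' @param taxon_a,taxon_b taxa to compare in every alignment.
#' @return data.frame with one row per gene (rows for genes where either
#'   taxon is absent are skipped with a warning).
#' @export
ng86_genewise <- function(alignments, taxon_a, taxon_b) {
  rows <- lapply(alignments, function(al) {
    if (!all(c(taxon_a, taxon_b) %in% names(al$seqs))) return(NULL)
    ng86_pairwise(al, taxon_a, taxon_b)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped) warning(sprintf("%d alignment(s) lacked the requested taxa", skipped))
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
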