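# mean nearest-neighbour distance of a set of 1-d positions
mean_nn_distance <- function(x) {
  x <- sort(x)
  gaps <- diff(x)
  mean(pmin(c(Inf, gaps), c(gaps, Inf)))
}

#' Monte-Carlo nearest-neighbour clustering test
#'
#' Tests whether positions are spatially clustered along a chromosome by
#' comparing their observed mean nearest-neighbour distance with that of
#' random draws from a mappable-position universe. Smaller-than-expected
#' distances indicate clustering. The p-value uses the add-one correction
#' p = (1 + #\{permutations <= observed\}) / (n_perm + 1) and can never be 0.
#'
#' @param positions observed positions (bp), at least 3.
#' @param universe positions from which random placements are drawn
#'   without replacement (typically the anchored-scaffold positions; a
#'   dense grid gives a uniform-bp null).
#' @param n_perm number of Monte-Carlo permutations (>= 1).
#' @param seed optional seed.
#' @return list with `observed_mean_nn`, `null_mean`, `p_value`, `n_perm`.
#' @export
nn_clustering_test <- function(positions, universe, n_perm = 999,
                               seed = NULL) {
  if (length(positions) < 3)
    stop("insufficient data: need at least 3 positions", call. = FALSE)
  if (!is.numeric(n_perm) || n_perm < 1)
    stop_field("n_perm", "must be >= 1")
  if (length(universe) < length(positions))
    stop("universe smaller than the observed position set", call. = FALSE)
  obs <- mean_nn_distance(positions)
  k <- length(positions)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i)
      mean_nn_distance(sample(universe, k)), numeric(1))
    list(observed_mean_nn = obs, null_mean = mean(null),
         p_value = (1 + sum(null <= obs)) / (n_perm + 1),
         n_perm = as.integer(n_perm))
  })
}

# exact DP over binned counts: best <= K segment piecewise-constant Poisson
# fit; returns boundaries (in bins) and log-likelihood per k
poisson_segment_dp <- function(counts, max_segments) {
  B <- length(counts)
  cs <- c(0, cumsum(counts))
  seg_ll <- function(i, j) {  # bins i..j
    n <- cs[j + 1] - cs[i]
    len <- j - i + 1
    if (n == 0) return(0)
    n * log(n / len) - n
  }
  # ll[k, j]: best log-lik of bins 1..j with k segments
  ll <- matrix(-Inf, max_segments, B)
  cut <- matrix(0L, max_segments, B)
  for (j in 1:B) ll[1, j] <- seg_ll(1, j)
  if (max_segments > 1) for (k in 2:max_segments) {
    for (j in k:B) {
      prev <- (k - 1):(j - 1)
      vals <- ll[k - 1, prev] + vapply(prev, function(m) seg_ll(m + 1, j),
                                       numeric(1))
      best <- which.max(vals)
      ll[k, j] <- vals[best]
      cut[k, j] <- prev[best]
    }
  }
  fits <- lapply(seq_len(max_segments), function(k) {
    bounds <- integer(0)
    j <- B
    kk <- k
    while (kk > 1) {
      bounds <- c(cut[kk, j], bounds)
      j <- cut[kk, j]
      kk <- kk - 1
    }
    list(k = k, loglik = ll[k, B], cut_bins = bounds)
  })
  fits
}

#' Segment the Z into evolutionary strata
#'
#' Either cuts at user-supplied boundaries (`method = "fixed"`) or finds
#' the best piecewise-constant Poisson segmentation of W-candidate density
#' with at most `max_segments` segments by exact dynamic programming over
#' `bin_width` bins, choosing the number of segments by BIC
#' (`method = "changepoint"`). Each segment reports its candidate count,
#' density per Mb and median Z-W identity (identities below
#' `min_identity`, indicating low-quality mapping, are excluded from the
#' median by default). Segments are labelled `"older"` (lowest density)
#' or `"younger"`.
#'
#' @param mapped data.frame with `z_position` and optionally `identity`.
#' @param method `"changepoint"` or `"fixed"`.
#' @param z_length chromosome length in bp (default: max position,
#'   rounded up to a bin).
#' @param boundaries for `"fixed"`: numeric vector of cut points in bp
#'   including 0 and the chromosome end (e.g. `c(0, 2e7, 5e7, 8e7)`).
#' @param max_segments for `"changepoint"`: maximum segments (default 3).
#' @param bin_width bin width in bp for the changepoint scan (default 1 Mb).
#' @param min_identity identities below this are flagged low-quality and
#'   excluded from segment medians (default 0.30).
#' @param all_fits if `TRUE`, attach every k-segment fit (1..max_segments)
#'   as attribute `"fits"` so e.g. 2- and 3-stratum solutions can be
#'   compared.
#' @return data.frame of `stratum_segment` rows: `start`, `end`,
#'   `n_candidates`, `density_per_mb`, `median_identity`, `label`.
#' @export
segment_strata <- function(mapped, method = c("changepoint", "fixed"),
                           z_length = NULL, boundaries = NULL,
                           max_segments = 3, bin_width = 1e6,
                           min_identity = 0.30, all_fits = FALSE) {
  method <- match.arg(method)
  check_columns(mapped, "z_position", "mapped")
  pos <- mapped$z_position
  ident <- if ("identity" %in% names(mapped)) mapped$identity
           else rep(NA_real_, length(pos))
  if (is.null(z_length)) z_length <- ceiling(max(pos) / bin_width) * bin_width

  summarize <- function(cuts) {  # cuts include 0 and z_length
    starts <- head(cuts, -1); ends <- tail(cuts, -1)
    seg <- findInterval(pos, cuts, rightmost.closed = TRUE)
    n <- tabulate(seg, length(starts))
    med_id <- vapply(seq_along(starts), function(s) {
      v <- ident[seg == s]
      median_or_na(v[!is.na(v) & v >= min_identity])
    }, numeric(1))
    dens <- n / ((ends - starts) / 1e6)
    data.frame(start = starts, end = ends, n_candidates = n,
               density_per_mb = dens, median_identity = med_id,
               label = ifelse(seq_along(starts) == which.min(dens),
                              "older", "younger"),
               stringsAsFactors = FALSE)
  }

  if (method == "fixed") {
    if (is.null(boundaries) || length(boundaries) < 2)
      stop("`boundaries` must give at least one interval", call. = FALSE)
    if (min(boundaries) < 0 || max(boundaries) > z_length)
      stop("boundaries outside chromosome", call. = FALSE)
    return(summarize(sort(unique(boundaries))))
  }

  if (length(pos) < 10)
    stop("changepoint mode needs at least 10 mapped positions", call. = FALSE)
  B <- ceiling(z_length / bin_width)
  counts <- tabulate(pmin(B, floor(pos / bin_width) + 1L), B)
  fits <- poisson_segment_dp(counts, max_segments)
  bic <- vapply(fits, function(f) -2 * f$loglik + (2 * f$k - 1) * log(B),
                numeric(1))
  best <- fits[[which.min(bic)]]
  cuts <- c(0, best$cut_bins * bin_width, z_length)
  out <- summarize(cuts)
  if (all_fits)
    attr(out, "fits") <- lapply(fits, function(f)
      summarize(c(0, f$cut_bins * bin_width, z_length)))
  out
}

#' Monte-Carlo cross-species overlap test for W-candidate positions
#'
#' Counts how many species-1 positions have at least one species-2
#' position within `window_bp` on the shared pseudochromosome, and
#' compares that overlap to a null in which both species' observed
#' numbers of positions are resampled from the universe of mappable
#' positions. Add-one-corrected p-value for an excess of overlap.
#'
#' @param positions_sp1,positions_sp2 candidate positions per species (bp).
#' @param window_bp maximum distance for two positions to count as
#'   overlapping.
#' @param universe mappable positions resampled under the null.
#' @param n_perm Monte-Carlo replicates.
#' @param seed optional seed.
#' @return list with `observed_overlap`, `null_mean`, `p_value`, `n_perm`;
#'   empty inputs give `status = "no data"`.
#' @export
cross_species_overlap_test <- function(positions_sp1, positions_sp2,
                                       window_bp, universe, n_perm = 999,
                                       seed = NULL) {
  if (!length(positions_sp1) || !length(positions_sp2))
    return(list(status = "no data", observed_overlap = 0L,
                p_value = NA_real_))
  if (!is.numeric(n_perm) || n_perm < 1) stop_field("n_perm", "must be >= 1")
  overlap <- function(a, b) {
    b <- sort(b)
    i <- findInterval(a, b)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(b))
    sum(abs(a - b[lo]) <= window_bp | abs(a - b[hi]) <= window_bp)
  }
  obs <- overlap(positions_sp1, positions_sp2)
  n1 <- length(positions_sp1); n2 <- length(positions_sp2)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i)
      overlap(sample(universe, n1), sample(universe, n2)), numeric(1))
    list(status = "ok", observed_overlap = obs, null_mean = mean(null),
         p_value = (1 + sum(null >= obs)) / (n_perm + 1),
         n_perm = as.integer(n_perm))
  })
}

#' Expected number of W genes shared between two species
#'
#' Under independent gene survival on the two W chromosomes, the expected
#' proportion of shared genes is the product of each species' proportion
#' of retained Z genes, so the expected shared count is
#' `n_w1 * n_w2 / n_total_z_genes`. The observed count is compared with a
#' 1-df chi-square goodness of fit over the shared / non-shared split of
#' the `n_total_z_genes` genes.
#'
#' @param n_w1,n_w2 numbers of Z genes retained on each species' W.
#' @param n_total_z_genes total number of Z-linked genes (the denominator;
#'   exposed explicitly because published gene universes differ).
#' @param observed_shared observed number of genes on both Ws.
#' @return list with `expected`, `observed`, `chi_square`, `p_value`.
#' @export
#' @examples
#' shared_gene_expectation(55, 29, 712, observed_shared = 15)
shared_gene_expectation <- function(n_w1, n_w2, n_total_z_genes,
                                    observed_shared) {
  if (!is.numeric(n_total_z_genes) || n_total_z_genes <= 0)
    stop_field("n_total_z_genes", "must be > 0")
  if (n_w1 > n_total_z_genes || n_w2 > n_total_z_genes)
    stop("retained counts cannot exceed the total gene number", call. = FALSE)
  if (observed_shared > min(n_w1, n_w2))
    stop("observed_shared cannot exceed min(n_w1, n_w2)", call. = FALSE)
  expected <- n_w1 * n_w2 / n_total_z_genes
  obs_vec <- c(observed_shared, n_total_z_genes - observed_shared)
  exp_vec <- c(expected, n_total_z_genes - expected)
  stat <- sum((obs_vec - exp_vec)^2 / exp_vec)
  list(expected = expected, observed = observed_shared, chi_square = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Gametolog tree-topology test
#'
#' Builds a neighbour-joining tree from Jukes-Cantor distances for a small
#' set of aligned Z- and W-derived sequences from two (or more) species
#' and asks whether the W sequences form a clade against the Z sequences
#' ("clusters by chromosome": recombination suppression predates the
#' species split) or whether within-species Z-W pairs cluster ("clusters
#' by species": suppression evolved independently). The tree is rooted on
#' `outgroup` when given, otherwise at its midpoint.
#'
#' @param alignment named character vector of equal-length aligned
#'   nucleotide sequences (4-5 taxa).
#' @param chromosome named character vector mapping each taxon to `"Z"`,
#'   `"W"` or `"outgroup"`.
#' @param species named character vector mapping each taxon to a species
#'   tag (used for the clusters-by-species verdict; optional).
#' @param outgroup taxon name to root on, or `NULL` for midpoint rooting.
#' @param min_columns minimum ungapped alignment columns (default 50);
#'   fewer gives verdict `"unresolved"` with a warning.
#' @return list with `tree` (ape `phylo`), `newick`, `verdict`
#'   (`"clusters-by-chromosome"`, `"clusters-by-species"` or
#'   `"unresolved"`) and `distances`.
#' @export
gametolog_topology_test <- function(alignment, chromosome, species = NULL,
                                    outgroup = NULL, min_columns = 50) {
  if (is.null(names(alignment)) || anyDuplicated(names(alignment)))
    stop("alignment sequences must have unique taxon names", call. = FALSE)
  if (length(alignment) < 4)
    stop("need at least 4 sequences (2 species x 2 chromosomes)", call. = FALSE)
  if (length(unique(nchar(alignment))) != 1L)
    stop("sequences must be aligned to equal length", call. = FALSE)
  chromosome <- chromosome[names(alignment)]
  mat <- t(vapply(strsplit(tolower(alignment), ""), identity,
                  character(nchar(alignment[1]))))
  ungapped <- apply(mat, 2, function(col) all(col %in% c("a", "c", "g", "t")))
  if (sum(ungapped) < min_columns) {
    warning(sprintf("only %d ungapped columns (< %d): verdict unresolved",
                    sum(ungapped), min_columns))
    return(list(tree = NULL, newick = NA_character_, verdict = "unresolved",
                distances = NULL))
  }
  dna <- ape::as.DNAbin(mat[, ungapped, drop = FALSE])
  d <- ape::dist.dna(dna, model = "JC69", pairwise.deletion = FALSE)
  if (any(!is.finite(d))) {
    warning("saturated Jukes-Cantor distance: verdict unresolved")
    return(list(tree = NULL, newick = NA_character_, verdict = "unresolved",
                distances = d))
  }
  tree <- ape::nj(d)
  rooted <- if (!is.null(outgroup)) {
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else phangorn::midpoint(tree)

  w_taxa <- names(chromosome)[chromosome == "W"]
  z_taxa <- names(chromosome)[chromosome == "Z"]
  verdict <- "unresolved"
  if (length(w_taxa) >= 2 &&
      ape::is.monophyletic(rooted, w_taxa)) {
    verdict <- "clusters-by-chromosome"
  } else if (!is.null(species)) {
    species <- species[names(alignment)]
    zw <- names(chromosome)[chromosome %in% c("Z", "W")]
    by_sp <- split(zw, species[zw])
    by_sp <- by_sp[vapply(by_sp, length, integer(1)) >= 2]
    if (length(by_sp) >= 2 &&
        all(vapply(by_sp, function(tx) ape::is.monophyletic(rooted, tx),
                   logical(1))))
      verdict <- "clusters-by-species"
  }
  list(tree = rooted, newick = ape::write.tree(rooted), verdict = verdict,
       distances = d)
}
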