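#' Configuration for the synthetic ZW-genome generator
#'
#' Bundles and validates every knob of the synthetic generators. Defaults
#' describe a snake-like genome with a fully differentiated Z: sequencing
#' depth 100 read pairs/kb per sex, 500 autosomal + 60 Z-linked scaffolds,
#' three evolutionary strata whose middle (oldest) stratum has the sparsest
#' and most diverged W survivors, a male:female mutation-rate ratio of 2,
#' partial expression buffering of the single female Z dose (median
#' log2(F/M) = -0.71) with 18% of Z genes individually compensated, and a
#' heterozygosity-free female Z.
#'
#' @param n_autosomal_scaffolds,n_z_scaffolds,n_w_scaffolds scaffold counts.
#' @param z_length length of the Z chromosome in bp.
#' @param depth mean read pairs per kb per sex (> 0).
#' @param nb_dispersion negative-binomial size parameter for count noise
#'   (larger = less overdispersion).
#' @param scaffold_length_range min/max scaffold length in bp (drawn
#'   uniformly).
#' @param w_mismap fraction of `depth` that leaks onto W scaffolds in the
#'   male sample (mismapping; 0 allowed).
#' @param strata data.frame with columns `start`, `end` (bp on the Z),
#'   `w_survival_prob`, `zw_identity`; intervals must be non-overlapping and
#'   inside `[0, z_length)`.
#' @param slot_spacing spacing in bp of W-survivor "gene slots" along the Z.
#' @param alpha_sim male:female mutation-rate ratio used by the codon
#'   generator (>= 0).
#' @param omega_target Ka/Ks acceptance probability for nonsynonymous
#'   changes in the codon generator.
#' @param branch_scale expected accepted substitutions per nucleotide site
#'   on each differentiated-lineage terminal branch; the default gives an
#'   autosomal pairwise Ks of about 0.2 between the two differentiated
#'   species.
#' @param buffering factor in `[0.5, 1]` scaling the expression deficit of
#'   one-dose Z genes: uncompensated Z genes have median log2(F/M) =
#'   `-buffering` (default 0.71; 1 would be a full two-fold reduction).
#' @param compensated_frac fraction of Z genes with restored (autosome-like)
#'   female expression.
#' @param expr_sd standard deviation (log2) of gene-wise F/M expression
#'   noise.
#' @param theta per-site heterozygosity, a named list of `c(f =, m =)`
#'   vectors for `autosome` and `z`; the default female Z value of 0
#'   encodes hemizygosity.
#' @param differentiated if `FALSE`, generate a boa-like genome: the Z is
#'   still labelled but has equal coverage in both sexes, no W scaffolds,
#'   no expression deficit and normal female Z heterozygosity.
#' @param seed integer seed; every generator is byte-reproducible under a
#'   fixed seed + config.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_autosomal_scaffolds = 500,
                       n_z_scaffolds = 60,
                       n_w_scaffolds = 50,
                       z_length = 8e7,
                       depth = 100,
                       nb_dispersion = 200,
                       scaffold_length_range = c(5e4, 5e5),
                       w_mismap = 0.01,
                       strata = default_strata(z_length),
                       slot_spacing = 4e4,
                       alpha_sim = 2,
                       omega_target = 0.15,
                       branch_scale = 0.034,
                       buffering = 0.71,
                       compensated_frac = 0.18,
                       expr_sd = 0.4,
                       theta = list(autosome = c(f = 0.005, m = 0.005),
                                    z = c(f = 0, m = 0.005)),
                       differentiated = TRUE,
                       seed = 1L) {
  if (!is.numeric(depth) || depth <= 0) stop_field("depth", "must be > 0")
  if (!is.numeric(z_length) || z_length <= 0) stop_field("z_length", "must be > 0")
  for (f in c("n_autosomal_scaffolds", "n_z_scaffolds", "n_w_scaffolds")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v != round(v)) stop_field(f, "must be a non-negative count")
  }
  if (!is.numeric(w_mismap) || w_mismap < 0 || w_mismap > 1)
    stop_field("w_mismap", "must be in [0, 1]")
  if (!is.numeric(buffering) || buffering < 0.5 - 1e-9 || buffering > 1 + 1e-9)
    stop_field("buffering", "must be in [0.5, 1]")
  if (!is.numeric(compensated_frac) || compensated_frac < 0 || compensated_frac > 1)
    stop_field("compensated_frac", "must be in [0, 1]")
  if (!is.numeric(alpha_sim) || alpha_sim < 0) stop_field("alpha_sim", "must be >= 0")
  if (!is.numeric(omega_target) || omega_target < 0) stop_field("omega_target", "must be >= 0")
  if (!is.numeric(scaffold_length_range) || length(scaffold_length_range) != 2L ||
      any(scaffold_length_range <= 0) ||
      scaffold_length_range[1] > scaffold_length_range[2])
    stop_field("scaffold_length_range", "must be two positive increasing lengths")
  strata <- validate_strata(strata, z_length)
  cfg <- list(n_autosomal_scaffolds = as.integer(n_autosomal_scaffolds),
              n_z_scaffolds = as.integer(n_z_scaffolds),
              n_w_scaffolds = as.integer(n_w_scaffolds),
              z_length = z_length, depth = depth,
              nb_dispersion = nb_dispersion,
              scaffold_length_range = scaffold_length_range,
              w_mismap = w_mismap, strata = strata,
              slot_spacing = slot_spacing, alpha_sim = alpha_sim,
              omega_target = omega_target, branch_scale = branch_scale,
              buffering = buffering, compensated_frac = compensated_frac,
              expr_sd = expr_sd, theta = theta,
              differentiated = isTRUE(differentiated),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default three-stratum layout for a synthetic Z
#'
#' The middle (oldest) stratum has the lowest W-survivor density and the
#' lowest Z-W identity; the distal regions are younger and denser.
#'
#' @param z_length Z length in bp.
#' @return data.frame with `start`, `end`, `w_survival_prob`, `zw_identity`.
#' @export
default_strata <- function(z_length = 8e7) {
  data.frame(start = c(0, 0.25, 0.625) * z_length,
             end = c(0.25, 0.625, 1) * z_length,
             w_survival_prob = c(0.2, 0.05, 0.3),
             zw_identity = c(0.50, 0.45, 0.55))
}

validate_strata <- function(strata, z_length) {
  if (is.null(strata) || !nrow(strata)) {
    warning("empty strata list: using a single stratum covering the whole Z")
    strata <- data.frame(start = 0, end = z_length,
                         w_survival_prob = 0.2, zw_identity = 0.5)
  }
  check_columns(strata, c("start", "end", "w_survival_prob", "zw_identity"),
                "strata")
  if (any(strata$start >= strata$end)) stop_field("strata", "start must be < end")
  if (any(strata$start < 0) || any(strata$end > z_length))
    stop_field("strata", "intervals must lie within [0, z_length]")
  if (any(strata$w_survival_prob < 0 | strata$w_survival_prob > 1))
    stop_field("strata", "w_survival_prob must be in [0, 1]")
  if (any(strata$zw_identity < 0 | strata$zw_identity > 1))
    stop_field("strata", "zw_identity must be in [0, 1]")
  o <- order(strata$start)
  strata <- strata[o, , drop = FALSE]
  if (nrow(strata) > 1L && any(strata$start[-1] < strata$end[-nrow(strata)]))
    stop_field("strata", "intervals must not overlap")
  rownames(strata) <- NULL
  strata
}

#' Simulate per-scaffold male/female read counts
#'
#' Autosomal scaffolds draw female and male counts from the same
#' negative-binomial distribution around `depth x length`; Z scaffolds draw
#' female counts at half the female rate (hemizygosity); W scaffolds are
#' present at half depth in the female and only at the mismapping rate in
#' the male. With `differentiated = FALSE` (boa-like) the Z behaves like an
#' autosome and no W scaffolds are emitted.
#'
#' @param config a [sim_config()].
#' @return list with `coverage` (data.frame: `scaffold_id`, `chrom`,
#'   `start`, `length`, `reads_f`, `reads_m`) and `truth` (data.frame:
#'   `scaffold_id`, `chrom`, `linkage_class`).
#' @export
simulate_coverage <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 101L), {
    n_a <- config$n_autosomal_scaffolds
    n_z <- config$n_z_scaffolds
    n_w <- if (config$differentiated) config$n_w_scaffolds else 0L
    n <- n_a + n_z + n_w
    lens <- round(stats::runif(n, config$scaffold_length_range[1],
                               config$scaffold_length_range[2]))
    class <- rep(c("autosome", "Z", "W"), c(n_a, n_z, n_w))
    chrom <- character(n)
    chrom[class == "autosome"] <- paste0("chr", 1 + (seq_len(n_a) - 1L) %% 5L)
    chrom[class == "Z"] <- "chrZ"
    chrom[class == "W"] <- NA_character_  # W scaffolds do not anchor
    start <- numeric(n)
    start[class == "autosome"] <- round(stats::runif(n_a, 0, 2e8))
    start[class == "Z"] <- round(stats::runif(n_z, 0, config$z_length))
    start[class == "W"] <- NA_real_

    f_factor <- ifelse(class == "autosome", 1,
                ifelse(class == "Z", if (config$differentiated) 0.5 else 1, 0.5))
    m_factor <- ifelse(class == "W", config$w_mismap, 1)
    mu <- config$depth * lens / 1000
    reads_f <- stats::rnbinom(n, mu = mu * f_factor, size = config$nb_dispersion)
    reads_m <- stats::rnbinom(n, mu = mu * m_factor, size = config$nb_dispersion)

    ids <- sprintf("scaffold_%04d", seq_len(n))
    list(coverage = data.frame(scaffold_id = ids, chrom = chrom, start = start,
                               length = lens, reads_f = reads_f,
                               reads_m = reads_m, stringsAsFactors = FALSE),
         truth = data.frame(scaffold_id = ids, chrom = chrom,
                            linkage_class = class, stringsAsFactors = FALSE))
  })
}

#' Simulate W-survivor content along the Z under an evolutionary-strata model
#'
#' Gene slots are placed every `slot_spacing` bp along the Z; a slot in
#' stratum *s* retains a W homolog with probability `w_survival_prob[s]`,
#' and each survivor is assigned a Z-W nucleotide identity drawn around
#' `zw_identity[s]`. Optionally emits actual Z/W sequence pairs at the
#' requested identity.
#'
#' @param config a [sim_config()].
#' @param identity_sd spread of identities around the stratum mean.
#' @param sequences if `TRUE`, also generate a random Z sequence per
#'   survivor and a W copy mutated to the drawn identity.
#' @param seq_length sequence length when `sequences = TRUE`.
#' @return list with `candidates` (data.frame: `candidate_id`,
#'   `z_position`, `identity`, `stratum`) and `truth` (the stratum table
#'   plus slot counts); when `sequences = TRUE` also `z_seq`/`w_seq`
#'   character vectors.
#' @export
simulate_strata_w_content <- function(config, identity_sd = 0.04,
                                      sequences = FALSE, seq_length = 300) {
  stopifnot(inherits(config, "sim_config"))
  strata <- config$strata
  with_seed(derive_seed(config$seed, 202L), {
    slots <- seq(config$slot_spacing / 2, config$z_length - 1,
                 by = config$slot_spacing)
    stratum_of <- findInterval(slots, strata$start)
    stratum_of[slots >= max(strata$end) | stratum_of < 1] <- NA
    keep <- !is.na(stratum_of)
    slots <- slots[keep]; stratum_of <- stratum_of[keep]
    surv <- stats::runif(length(slots)) < strata$w_survival_prob[stratum_of]
    pos <- slots[surv]
    str_id <- stratum_of[surv]
    ident <- pmin(1, pmax(0, stats::rnorm(length(pos),
                                          strata$zw_identity[str_id],
                                          identity_sd)))
    ident[strata$zw_identity[str_id] == 1] <- 1
    out <- list(candidates = data.frame(
                  candidate_id = sprintf("wcand_%04d", seq_along(pos)),
                  z_position = pos, identity = ident, stratum = str_id,
                  stringsAsFactors = FALSE),
                truth = cbind(strata,
                              n_slots = tabulate(stratum_of, nrow(strata)),
                              n_survivors = tabulate(str_id, nrow(strata))))
    if (sequences) {
      bases <- c("A", "C", "G", "T")
      z_seq <- vapply(seq_along(pos), function(i)
        paste(sample(bases, seq_length, replace = TRUE), collapse = ""),
        character(1))
      w_seq <- vapply(seq_along(pos), function(i) {
        ch <- strsplit(z_seq[i], "")[[1]]
        mut <- which(stats::runif(seq_length) > ident[i])
        if (length(mut))
          ch[mut] <- vapply(ch[mut], function(b)
            sample(setdiff(bases, b), 1), character(1))
        paste(ch, collapse = "")
      }, character(1))
      out$z_seq <- stats::setNames(z_seq, out$candidates$candidate_id)
      out$w_seq <- stats::setNames(w_seq, out$candidates$candidate_id)
    }
    out
  })
}

# --- codon-alignment generator ----------------------------------------------

# Evolve an integer codon vector along one branch: `n_sub` accepted
# substitutions; proposals are uniform single-nucleotide changes, accepted
# with probability 1 (synonymous), `omega` (nonsynonymous) or 0 (stop).
evolve_codons <- function(cod, n_sub, omega, tab) {
  if (n_sub <= 0) return(cod)
  L <- length(cod)
  accepted <- 0L
  # pre-draw proposal randomness in blocks to keep the loop tight
  block <- max(16L, ceiling(n_sub * 3.5))
  repeat {
    sites <- sample.int(3L * L, block, replace = TRUE)
    shifts <- sample.int(3L, block, replace = TRUE)
    us <- stats::runif(block)
    for (k in seq_len(block)) {
      s <- sites[k]
      ci <- (s - 1L) %/% 3L + 1L
      pos <- (s - 1L) %% 3L + 1L
      old <- cod[ci] - 1L
      p4 <- 4L^(3L - pos)
      base <- (old %/% p4) %% 4L
      newbase <- (base + shifts[k]) %% 4L
      newcod <- old + (newbase - base) * p4 + 1L
      a_old <- tab$aa[cod[ci]]
      a_new <- tab$aa[newcod]
      if (a_new == "*") next
      if (a_old == a_new || us[k] < omega) {
        cod[ci] <- newcod
        accepted <- accepted + 1L
        if (accepted >= n_sub) return(cod)
      }
    }
  }
}

#' Simulate codon alignments with faster-Z substitution scaling
#'
#' Generates, per gene, an aligned codon set for four taxa: an outgroup,
#' a homomorphic lineage (boa-like) and two differentiated lineages
#' (viper-like and colubrid-like). Substitutions are placed per branch at
#' rates proportional to branch length; on the two differentiated terminal
#' branches and their shared internal branch, Z-linked genes are scaled by
#' ((2 alpha + 1)/3) / ((alpha + 1)/2) relative to autosomal genes -- the
#' Z:autosome per-generation rate ratio implied by a male:female
#' mutation-rate ratio `alpha_sim`. Nonsynonymous changes are accepted with
#' probability `omega_target`; changes creating stop codons are rejected.
#'
#' @param config a [sim_config()].
#' @param n_genes number of genes (> 0).
#' @param codons_per_gene codons per gene (>= 10).
#' @param prop_z fraction of genes that are Z-linked (default 0.5).
#' @return list with `alignments` (list of [codon_alignment()]; taxa
#'   `outgroup`, `homomorphic`, `differentiated1`, `differentiated2`) and
#'   `truth` (data.frame `gene_id`, `class`, plus the generating `alpha`).
#' @export
simulate_codon_alignments <- function(config, n_genes, codons_per_gene,
                                      prop_z = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(n_genes) || n_genes < 1) stop_field("n_genes", "must be > 0")
  if (!is.numeric(codons_per_gene) || codons_per_gene < 10)
    stop_field("codons_per_gene", "must be >= 10 for meaningful divergence")
  tab <- ng86_tables()
  nonstop <- which(tab$aa != "*")
  zf <- z_autosome_rate_scaling(config$alpha_sim)
  b <- config$branch_scale
  # expected accepted substitutions per nucleotide, per branch:
  #   root->outgroup, root->homomorphic, root->anc12, anc12->tip (x2)
  branch_nt <- c(out = 6 * b, homo = 3 * b, anc = b, tip = b)
  with_seed(derive_seed(config$seed, 303L), {
    n_z <- round(n_genes * prop_z)
    classes <- rep(c("Z", "autosome"), c(n_z, n_genes - n_z))
    L_nt <- 3 * codons_per_gene
    alignments <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      scale <- if (classes[g] == "Z") zf else 1
      anc <- sample(nonstop, codons_per_gene, replace = TRUE)
      # realized substitution count per branch: expected value b * L_nt,
      # stochastically rounded so the mean is exact for any scaling; keeps
      # per-gene divergence variance down to site-sampling noise
      n_sub <- function(len_nt) {
        lambda <- len_nt * L_nt
        floor(lambda) + stats::rbinom(1, 1, lambda - floor(lambda))
      }
      outg <- evolve_codons(anc, n_sub(branch_nt["out"]), config$omega_target, tab)
      homo <- evolve_codons(anc, n_sub(branch_nt["homo"]), config$omega_target, tab)
      anc12 <- evolve_codons(anc, n_sub(branch_nt["anc"] * scale),
                             config$omega_target, tab)
      d1 <- evolve_codons(anc12, n_sub(branch_nt["tip"] * scale),
                          config$omega_target, tab)
      d2 <- evolve_codons(anc12, n_sub(branch_nt["tip"] * scale),
                          config$omega_target, tab)
      seqs <- vapply(list(outgroup = outg, homomorphic = homo,
                          differentiated1 = d1, differentiated2 = d2),
                     function(v) paste(tab$codons[v], collapse = ""),
                     character(1))
      alignments[[g]] <- codon_alignment(seqs, gene_id = sprintf("gene_%05d", g),
                                         class = classes[g])
    }
    list(alignments = alignments,
         truth = data.frame(gene_id = sprintf("gene_%05d", seq_len(n_genes)),
                            class = classes, alpha = config$alpha_sim,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a male/female expression table
#'
#' Autosomal genes have equal expected expression in both sexes (log-normal
#' gene-wise noise). On a differentiated Z, uncompensated genes have female
#' expression reduced to `2^-buffering` of the male level (partial
#' buffering of the lost dose); a `compensated_frac` subset keeps
#' autosome-like female expression. With `differentiated = FALSE` the Z
#' behaves like an autosome.
#'
#' @param config a [sim_config()].
#' @param n_auto,n_z numbers of autosomal and Z-linked genes.
#' @return list with `expression` (data.frame: `gene_id`, `chrom`,
#'   `pos`, `fpkm_f`, `fpkm_m`) and `truth` (adds `true_log2_dose` and
#'   `compensated`).
#' @export
simulate_expression <- function(config, n_auto = 2000, n_z = 400) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 404L), {
    n <- n_auto + n_z
    class <- rep(c("autosome", "Z"), c(n_auto, n_z))
    chrom <- ifelse(class == "autosome",
                    paste0("chr", 1 + (seq_len(n) - 1L) %% 5L), "chrZ")
    pos <- numeric(n)
    pos[class == "autosome"] <- round(stats::runif(n_auto, 0, 2e8))
    pos[class == "Z"] <- round(stats::runif(n_z, 0, config$z_length))
    compensated <- rep(FALSE, n)
    if (config$differentiated && n_z > 0)
      compensated[class == "Z"] <- stats::runif(n_z) < config$compensated_frac
    dose <- ifelse(class == "Z" & config$differentiated & !compensated,
                   -config$buffering, 0)
    base <- stats::rlnorm(n, meanlog = 2.5, sdlog = 1.1)
    noise <- stats::rnorm(n, 0, config$expr_sd)
    fpkm_m <- base
    fpkm_f <- base * 2^(dose + noise)
    ids <- sprintf("expr_%05d", seq_len(n))
    list(expression = data.frame(gene_id = ids, chrom = chrom, pos = pos,
                                 fpkm_f = fpkm_f, fpkm_m = fpkm_m,
                                 stringsAsFactors = FALSE),
         truth = data.frame(gene_id = ids, chrom = chrom, class = class,
                            true_log2_dose = dose, compensated = compensated,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate per-site base-count pileup profiles per sex
#'
#' Heterozygous sites are planted at the per-site rate `theta` for the
#' gene's chromosome class and sex (a hemizygous female Z has theta = 0 by
#' default); at heterozygous sites read counts split between two bases
#' with allele balance ~0.5, elsewhere a small sequencing error rate
#' scatters non-reference counts.
#'
#' @param config a [sim_config()].
#' @param genes data.frame with `gene_id` and `class` (`"autosome"`/`"Z"`).
#' @param sites_per_gene sites simulated per gene.
#' @param mean_coverage mean per-site coverage (Poisson).
#' @param error_rate per-base sequencing error rate.
#' @return data.frame: `gene_id`, `site`, `sex` (`"f"`/`"m"`), `A`, `C`,
#'   `G`, `T`.
#' @export
simulate_pileups <- function(config, genes, sites_per_gene = 120,
                             mean_coverage = 30, error_rate = 0.002) {
  stopifnot(inherits(config, "sim_config"))
  check_columns(genes, c("gene_id", "class"), "genes")
  with_seed(derive_seed(config$seed, 505L), {
    rows <- vector("list", nrow(genes) * 2L)
    k <- 0L
    for (i in seq_len(nrow(genes))) {
      cls <- if (genes$class[i] == "Z") "z" else "autosome"
      for (sex in c("f", "m")) {
        th <- config$theta[[cls]][[sex]]
        if (cls == "z" && sex == "f" && !config$differentiated)
          th <- config$theta[["autosome"]][["f"]]
        cov <- stats::rpois(sites_per_gene, mean_coverage)
        het <- stats::runif(sites_per_gene) < th
        counts <- matrix(0L, sites_per_gene, 4L,
                         dimnames = list(NULL, c("A", "C", "G", "T")))
        ref <- sample.int(4L, sites_per_gene, replace = TRUE)
        alt <- 1L + (ref + sample.int(3L, sites_per_gene, replace = TRUE) - 1L) %% 4L
        for (s in seq_len(sites_per_gene)) {
          if (cov[s] == 0L) next
          err <- stats::rbinom(1L, cov[s], error_rate)
          good <- cov[s] - err
          if (het[s]) {
            a1 <- stats::rbinom(1L, good, 0.5)
            counts[s, ref[s]] <- a1
            counts[s, alt[s]] <- good - a1
          } else counts[s, ref[s]] <- good
          if (err > 0) {
            spill <- stats::rmultinom(1L, err, rep(1, 4))[, 1]
            counts[s, ] <- counts[s, ] + spill
          }
        }
        k <- k + 1L
        rows[[k]] <- data.frame(gene_id = genes$gene_id[i],
                                site = seq_len(sites_per_gene), sex = sex,
                                A = counts[, 1], C = counts[, 2],
                                G = counts[, 3], T = counts[, 4],
                                stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows[seq_len(k)])
  })
}

#' Write a full synthetic bundle to disk
#'
#' Runs every generator under one config and writes coverage, expression
#' and pileup TSVs, per-gene alignment FASTAs, a W-candidate BED-like file
#' and a truth JSON to `dir`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @param n_genes,codons_per_gene codon-generator size (kept small by
#'   default; scale up for rate analyses).
#' @return invisibly, a named list of the paths written.
#' @export
simulate_zw_bundle <- function(config, dir, n_genes = 60,
                               codons_per_gene = 100) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cov <- simulate_coverage(config)
  wc <- simulate_strata_w_content(config)
  expr <- simulate_expression(config)
  pick <- c(which(expr$truth$class == "autosome")[1:20],
            which(expr$truth$class == "Z")[1:20])
  pick <- pick[!is.na(pick)]
  genes <- expr$truth[pick, c("gene_id", "class")]
  pile <- simulate_pileups(config, genes)
  cod <- simulate_codon_alignments(config, n_genes, codons_per_gene)

  paths <- list(coverage = file.path(dir, "coverage.tsv"),
                expression = file.path(dir, "expression.tsv"),
                pileup = file.path(dir, "pileup.tsv"),
                w_candidates = file.path(dir, "w_candidates.bed"),
                truth = file.path(dir, "truth.json"),
                alignments = file.path(dir, "alignments"))
  write_tsv_table(cov$coverage, paths$coverage)
  write_tsv_table(expr$expression, paths$expression)
  write_tsv_table(pile, paths$pileup)
  bed <- data.frame(chrom = "chrZ", start = wc$candidates$z_position,
                    end = wc$candidates$z_position + 1,
                    name = wc$candidates$candidate_id,
                    score = wc$candidates$identity, strand = "+")
  write_bed_like(bed, paths$w_candidates)
  dir.create(paths$alignments, showWarnings = FALSE)
  for (al in cod$alignments)
    write_fasta_alignment(al, file.path(paths$alignments,
                                        paste0(al$gene_id, ".fasta")))
  truth <- list(coverage = cov$truth, strata = wc$truth,
                expression = expr$truth, codon = cod$truth)
  jsonlite::write_json(truth, paths$truth, dataframe = "columns", digits = NA)
  invisible(paths)
}
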