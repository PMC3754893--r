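---
title: "Methods: coverage-based ZW analysis, strata, divergence and dosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based ZW analysis, strata, divergence and dosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zwdiff)
```

zwdiff analyses female-heterogametic (ZW) genomes from male/female
sequencing data. This vignette records the models behind each stage, the
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical choices that a reviewer or maintainer would
otherwise have to reverse-engineer.

## Coverage-based identification of the Z

In a ZW female the Z is present in one copy and a degenerate W contributes
no reads mapping to Z scaffolds, so female genomic coverage of
differentiated Z sequence is half the male level, while autosomes and any
still-recombining pseudoautosomal region (PAR) are equal in both sexes.
`normalize_coverage()` converts per-scaffold read counts to coverage
(reads/length), divides each scaffold-by-sex coverage by the median
autosomal coverage of that sex, and takes log2. Because the transform is
monotone, the autosomal median is exactly 0 in each sex whenever the number
of autosomal scaffolds with nonzero counts is odd (the median is then an
actual scaffold; with an even count it is the midpoint of two scaffolds and
sits within numerical noise of 0). Hemizygous scaffolds are expected at
log2 = -1 in the female.

`classify_linkage()` calls a chromosome Z-linked when its median
female-minus-male log2 coverage falls below `z_threshold = -0.5`. The
threshold is a documented package choice, not a literature value: it splits
the autosomal expectation (0) and the hemizygous expectation (-1)
symmetrically. Scaffolds on a Z chromosome whose smoothed profile stays at
or above -0.25 are flagged for PAR screening rather than silently
reclassified. Smoothing defaults to a running median over 41 scaffolds
(`smooth_along_chromosome()`): unlike a smoothing spline it has no free
bandwidth parameter and is reproducible to the bit; a spline mode is
available for plotting.

A scaffold with zero reads in one sex gets a missing value, never
`-Inf`, and is excluded from the medians of that sex.

## Scaffold anchoring

`assign_scaffold()` places a de novo scaffold on a reference chromosome by
the modal chromosome among its homology hits. Hits on the consensus
chromosome farther than 1 Mb from their nearest neighbour in the group are
discarded as spurious mappings (single pass); the anchor is the median
retained position; the orientation is the sign consensus of colinearity
between the hit order (gene order along the scaffold — the input contract)
and the reference positions. Two deliberate conservative choices: a modal
tie yields `"unplaced"` rather than an arbitrary pick, and an equal number
of concordant and discordant pairs yields orientation `"unknown"` with the
scaffold kept in its given polarity. `build_pseudochromosome()` concatenates
anchored scaffolds in anchor order; all coordinates in the package are
0-based, half-open, and the map is invertible (round-trip tested).

## W-candidate detection

Three detectors mirror three evidence types, all with strict inequalities
exactly as the thresholds are conventionally printed:

* **Scaffolds** (`detect_female_biased_scaffolds()`): the female proportion
  of coverage is computed from per-sex median-normalized coverages, so a
  larger female library cannot masquerade as female bias; a scaffold is a
  candidate when its fraction exceeds the Tukey fence Q3 + 1.5 x IQR of
  the autosomal fractions. Under a null genome with no W this flags on the
  order of 1-3% of scaffolds — the ordinary Tukey false-positive rate —
  which is why candidates are subsequently *mapped* and tested for Z
  enrichment rather than trusted individually.
* **Genes** (`detect_w_gene_scaffolds()`): female read count above 20 and
  male read count below 2, on mismatch-filtered counts (the upstream
  aligner contract).
* **Transcripts** (`detect_w_transcripts()`): male/female genomic count
  ratio below 0.1, female count above 30, and female-specific expression,
  operationalised strictly as male FPKM equal to 0 with female FPKM
  positive. The zero-male-FPKM reading is the strictest one; the threshold
  is a parameter for users who prefer a small epsilon.

`map_candidates_and_test_enrichment()` keeps the best alignment per
candidate (most aligned nucleotides; ties by identity, then id, for
determinism), requires more than 150 aligned nucleotides by default
(`strict` preset: >= 200 nt and identity > 30%; `lenient`: >= 100 nt), and
tests the observed Z-mapped proportion against the Z's size share with a
two-sided binomial test. The fold excess is observed/expected — e.g. 49%
observed against a 7.6% share is a 6.4-fold excess.

## Evolutionary strata

Regions of the Z that stopped recombining with the W at different times
("strata") differ in the density of surviving W homologs and in Z-W
nucleotide identity. `nn_clustering_test()` is a Monte-Carlo test of
spatial clustering: the observed mean nearest-neighbour distance of mapped
W candidates is compared with placements drawn without replacement from a
mappable-position universe. The universe defaults to the positions of all
anchored scaffolds rather than uniform base pairs, so assembly gaps and
anchoring density cannot manufacture clustering; a uniform-bp universe is a
one-line alternative. All Monte-Carlo p-values use the add-one correction
`(1 + k)/(n_perm + 1)` and can never be 0.

`segment_strata()` has two modes. Fixed mode reproduces equal-interval
analyses at user boundaries. Changepoint mode is this package's own
addition: an exact dynamic program maximises the piecewise-constant
Poisson-rate likelihood of 1 Mb bin counts for every segment number up to
`max_segments` (default 3), and BIC with 2k-1 parameters picks the segment
number. Identities below 30% are flagged low-quality mapping and excluded
from segment medians by default. Whether the two distal regions form one
stratum or two is often genuinely unresolved; `all_fits = TRUE` returns
the 2- and 3-segment solutions side by side so users can report both.

Two cross-species operations ask whether recombination suppression predates
a species split: `cross_species_overlap_test()` resamples both species'
observed candidate counts from the shared universe and counts species-1
positions with a species-2 position within `window_bp`; and
`shared_gene_expectation()` compares the observed number of genes retained
on both W chromosomes with the independence expectation
`n_w1 * n_w2 / n_total` (1-df chi-square). The denominator is an explicit
argument because published gene universes for the same chromosome differ
between assemblies; the function reports whatever denominator it is given.

`gametolog_topology_test()` builds a neighbour-joining tree (ape) from
Jukes-Cantor distances for 4-5 aligned Z/W sequences from two species,
roots on the outgroup when given (midpoint otherwise), and reports
`clusters-by-chromosome` when the W sequences are monophyletic — the
signature of suppression before the species split — versus
`clusters-by-species` when within-species Z-W pairs are. Alignments with
fewer than 50 ungapped columns, or with a saturated distance, are
`unresolved` rather than guessed.

## Codon divergence and male-driven evolution

`ng86_pairwise()` implements the Nei-Gojobori (1986) counting method:
synonymous (S) and nonsynonymous (N) site counts by per-codon degeneracy
fractions averaged over the two sequences; observed differences classified
by equal-weight averaging over all shortest mutational pathways; and
Jukes-Cantor correction d = -(3/4) ln(1 - 4p/3) of both proportions.
Conventions that matter and are therefore fixed here:

* Single-nucleotide changes that create a stop codon count as
  nonsynonymous in the site tally (this is the convention under which the
  classic worked example TTT vs TTA gives S = 0.5, N = 2.5, Ka ~ 0.5716).
* Pathways passing through a stop codon are excluded and the remaining
  pathway weights renormalised; in the rare codon pairs where every
  pathway passes a stop, all pathways are kept with stop steps counted
  nonsynonymous, rather than dropping the codon.
* A proportion at or beyond the Jukes-Cantor pole (p >= 3/4) flags the
  corresponding rate as saturated/undefined instead of returning a
  negative or infinite value. A class with zero sites in the overlap
  necessarily has zero differences and reports a rate of 0.
* Gapped or ambiguous codon columns are dropped pairwise and counted.
* omega = Ka/Ks is missing when Ks = 0.

The implementation precomputes 64 x 64 pathway-averaged difference tables
once per session, which makes genome-scale gene sets cheap; the test suite
verifies it against an independent exhaustive-pathway enumeration on short
alignments, exactly.

Faster-Z comparisons use per-gene ratios of rates between species pairs
sharing an outgroup (`lineage_rate_ratios()`), compared between Z and
autosomes with a two-sided rank-sum test (`faster_z_test()`); medians, not
means, summarise chromosome classes throughout, as is standard for
long-tailed rate distributions.

Because the Z is transmitted through males two thirds of the time and
autosomes half of the time, neutral divergence scales as (2a+1)/3 on the Z
and (a+1)/2 on autosomes, where a is the male:female mutation-rate ratio.
`estimate_alpha()` inverts this: a = (3KsZ - 2KsA)/(4KsA - 3KsZ), defined
only while KsZ/KsA < 4/3 (the ratio's saturation value, reached as a goes
to infinity). The estimator is exact for any positive rate scale — the
closed-form identity is part of the test suite — but is very sensitive
near saturation: a +/-1% error in the Ks ratio moves a by roughly +/-0.15
around a = 2, which is why genome-scale gene counts are needed for a
stable estimate.

## SNP-based verification of hemizygosity

A truly hemizygous female Z cannot be heterozygous. `call_snps()` applies
a deliberately simple rule to per-site base counts: sites with coverage
strictly over 10 are kept, and a site is a SNP when at least two bases
each exceed 0.3 x coverage. The frequency comparison is done in integer
arithmetic (`10 * count > 3 * coverage`), so a count exactly at the
boundary can never flip on floating-point rounding; at most three bases
can simultaneously exceed the threshold. `gene_snp_summary()` reports, per
chromosome class and sex, the proportion of genes with at least one SNP
among genes with at least one qualifying site — genes with no covered site
are excluded from the denominator, which is the package's documented
convention where published denominators are ambiguous. `het_ratio()`
compares mean per-gene SNP density (SNPs per qualifying site, decoupling
the statistic from gene length) between Z and autosomes with a gene-level
bootstrap, against the neutral copy-number expectation of 0.75 (three Z
copies per breeding pair versus four autosome copies).

## Dosage compensation

`chromosome_expression_summary()` reports per-chromosome medians of female
and male expression and of the per-gene log2(F/M) ratio, with rank-sum
tests of the Z against pooled autosomes for each. A ratio is defined only
when both sexes exceed the cutoff — a ratio forces the both-sexes
requirement even under a "FPKM > 0" filter — and no pseudocounts are used;
genes expressed in one sex only are excluded from ratio statistics, not
imputed. Passing `cutoffs = c(0, 1, 10)` reproduces the robustness sweep
across expression filters. `fold_change()` converts a median log2 ratio to
a fold difference (2^|m|; -0.71 is a 1.6-fold reduction at two significant
figures). `sliding_window_ratio()` slides a 30-gene window one gene at a
time (the step is a choice; it is not dictated by the window size) and
`compensated_fraction()` counts genes within +/-0.3 log2 units of parity —
about 0.8 < F/M < 1.2 — optionally testing whether compensated genes
cluster positionally with the same nearest-neighbour machinery used for
strata.

## The synthetic generator: what it emulates, and what it does not

Every stage is exercised against `sim_config()` genomes with known truth.
Defaults describe the study conditions the package validates against:
sequencing depth 100 read pairs/kb per sex; 500 autosomal, 60 Z and 50 W
scaffolds of 50-500 kb; three strata on an 80 Mb Z — (0-20 Mb, survival
0.2, identity 0.50), (20-50 Mb, 0.05, 0.45), (50-80 Mb, 0.3, 0.55) — so
the middle stratum is the oldest; a male:female mutation-rate ratio of 2;
partial dosage buffering with median log2(F/M) = -0.71 on the
uncompensated Z and 18% of Z genes compensated; and a heterozygosity-free
female Z. `differentiated = FALSE` flips the whole genome to a
homomorphic (boa-like) control: equal-sex Z coverage, no W scaffolds, no
expression deficit, normal female Z heterozygosity.

Choices the numbers depend on:

* **Count noise** is negative binomial with dispersion `nb_dispersion`
  (default 200, i.e. ~7% extra-Poisson coverage noise per scaffold):
  sequencing coverage is overdispersed, and a dispersion knob lets users
  stress the classifier.
* **W mismapping** puts 1% of depth onto W scaffolds in the male by
  default, so W detection is not trivially "zero male reads"; set it to 0
  for the idealised case.
* **Buffering** is implemented as shrinkage of the -1 log2 dose effect to
  `-buffering` (default -0.71), with a `compensated_frac` subset restored
  to parity. This reproduces the observed expression pattern without
  modelling its regulatory mechanism, which is out of scope.
* **Codon evolution** is a mutate-then-classify scheme, not a full codon
  model: proposals are uniform single-nucleotide changes; synonymous
  proposals are always accepted, nonsynonymous ones with probability
  `omega_target` (0.15), stops never. Z-linked genes scale the two
  differentiated terminal branches and their shared internal branch by
  ((2a+1)/3)/((a+1)/2). Branch lengths are *realized* substitution counts
  (expected value times sequence length, stochastically rounded so the
  mean is exact): the generator exists to validate estimators, so
  per-gene divergence variance is kept at the site-sampling floor rather
  than inflated by Poisson variation in the substitution count itself.
  Defaults give an autosomal Ks of about 0.2 between the two
  differentiated lineages.
* **Pileups** plant heterozygous sites at rate `theta` per class and sex
  with 0.5 allele balance, Poisson coverage (mean 30) and a 0.2%
  sequencing error rate — far below the 30% frequency needed to fake a
  SNP call.

The generator does **not** emulate: read-level artefacts (it draws counts,
not reads), repeat-driven mismapping structure, assembly fragmentation
bias, recombination/coalescent genealogies, indels in codon alignments, or
parasite contamination of transcriptomes. Passing tests therefore show
that the estimators invert the stated generative models at realistic noise
levels — not that they are robust to every artefact of real libraries.

## Validation problem sizes

The shipped test suite runs, among others: normalization identities on
500 + 60 scaffolds; the full alpha chain on 2000 genes x 300 codons
(recovering a = 2 within +/-0.2); changepoint recovery of the planted
20/50 Mb boundaries within +/-3 Mb in at least 90 of 100 seeded genomes;
a 500-replicate calibration of the nearest-neighbour test at n_perm = 999
(type-I error 0.05 +/- 0.02); exhaustive SNP-rule verification over every
base-count vector with coverage <= 30; recovery of 12 planted W
transcripts among 10,000 with zero false positives; and 100 gametolog
simulations with pre-speciation suppression (at least 95 must cluster by
chromosome). These sizes were chosen so each check is statistically
decisive for the property it tests.

## Known limitations

* Coverage classification assumes the W is degenerate enough not to
  attract female reads onto Z scaffolds; a young, high-identity W
  compresses the female deficit towards 0 and the -0.5 threshold becomes
  conservative.
* A sex-determining region translocated to a chromosome not represented
  in the anchoring reference is invisible to every stage (the anchoring
  is only as good as the homology map).
* The alpha estimator attributes the whole Z/A synonymous-rate difference
  to male-biased mutation; selection on synonymous sites or GC-biased
  gene conversion would bias it.
* Changepoint segmentation assumes piecewise-constant candidate density;
  gradual decay of W survivorship will be approximated by steps.
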