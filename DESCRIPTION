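Package: zwdiff
Title: Comparative ZW Sex-Chromosome Differentiation from Coverage,
    Divergence and Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying and characterising ZW sex chromosomes in
    female-heterogametic genomes from male/female sequencing data. Assigns
    de novo scaffolds to reference chromosomes by homology consensus,
    classifies Z-linked sequence from sex-specific read coverage, detects
    W-linked candidate scaffolds, genes and transcripts, tests for
    evolutionary strata along the Z (Monte-Carlo nearest-neighbour
    clustering, Poisson changepoint segmentation, gametolog tree topology),
    estimates codon-level divergence with the Nei-Gojobori (1986) method,
    quantifies faster-Z evolution and the male-to-female mutation-rate
    ratio, calls SNPs from per-site pileup profiles to verify hemizygosity,
    and measures dosage compensation from male/female expression. Includes
    a seeded synthetic ZW-genome generator so every stage can be exercised
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    phangorn,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
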