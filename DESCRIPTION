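Package: adintro
Title: Adaptive Introgression Tests for Resistance Genes in Hybridizing Species Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether a class of loci (for example plant disease-resistance
    genes) introgresses between two hybridizing species at a higher rate than reference
    loci. Computes per-locus diversity and divergence statistics from coding-frame
    alignments (segregating sites, haplotype counts, Jukes-Cantor corrected synonymous,
    nonsynonymous and total nucleotide diversity via Nei-Gojobori site counting,
    Hudson-Kaplan minimum recombination events, fixed/shared/private polymorphism
    partitions, and interspecific Ks/Kn divergence extremes), classifies loci as carrying
    trans-specific polymorphism from neighbor-joining trees, and compares the observed
    number of loci with identical interspecific sequences against a two-population
    isolation-with-migration coalescent null simulated over a parameter grid, with
    envelope, Fisher-exact and permutation tests. Includes a synthetic-data generator
    that emulates the study design with known planted ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
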