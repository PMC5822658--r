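Package: teratornscan
Title: Detection and Characterization of Teratorn-Like Endogenous
    Herpesviruses in Fish Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for discovering Teratorn-like
    herpesvirus endogenous viral elements (EVEs) in teleost genome
    assemblies. Provides a six-frame translated homology search of
    viral protein queries against nucleotide contigs, merging of gene
    hits into candidate element loci, core-gene presence
    classification, subtype clustering by pairwise nucleotide
    identity, coverage-ratio copy-number estimation against a
    mask-and-append reference, annotation of piggyBac-transposase
    fusion, terminal inverted repeats, target-site duplications and
    ORF intactness, Kimura two-parameter distances, modified
    Nei-Gojobori dN/dS, neighbor-joining trees with bootstrap, and
    Robinson-Foulds congruence testing between transposase and viral
    gene phylogenies. Includes a synthetic-genome generator with
    planted elements and a truth table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
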