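Package: oligosig
Title: Oligonucleotide Signature Analysis for Taxonomic Classification of
    Genomes and Metagenome Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes oligonucleotide usage signatures (word lengths 1-9)
    for genomes, fragments and scaffolds with an overlapping sliding
    window, derives Euclidean distance matrices and neighbor-joining
    cladograms, and scores taxonomic resolving power via nearest-neighbor
    agreement, leave-one-out distance histograms, a random-mutation
    divergence simulation, fragment-length and chunk-distance experiments,
    and composition-based best-hit binning. Includes a hierarchical
    synthetic community simulator (rank-structured perturbed Markov
    sequence models) for end-to-end evaluation without external genome
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
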