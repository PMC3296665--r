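Package: pyroseval
Title: Simulation-Based Evaluation of Pyrosequencing Strategies for
    Prokaryotic Genome Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how single-end and paired-end 454-style
    pyrosequencing strategies determine the quality of de novo prokaryotic
    genome assemblies.  Generates synthetic circular genomes with planted
    gene and repeat annotations, simulates flow-cycle reads with a
    homopolymer-aware error model and a Monte-Carlo paired-end library
    procedure, assembles reads with a greedy overlap assembler and
    paired-end scaffolder, scores assemblies against their reference
    (genome coverage, substitution and indel error rates, N50, contig and
    scaffold counts, false gene duplication and loss), summarises genome
    repeat content in the >300 bp and >700 bp classes, and regresses
    assembly quality indicators on repeat-content indicators across a
    genome panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
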