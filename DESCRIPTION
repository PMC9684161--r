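Package: SGBkit
Title: Species-Level Genome Bin Construction and Profiling for
    Metagenome-Assembled Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to dereplicate metagenome-assembled genomes (MAGs) and
    reference genomes into species-level genome bins (SGBs) and to profile
    their abundance across metagenomic samples. Implements bottom-s MinHash
    sketching of canonical k-mers with Mash distance estimation,
    average-linkage pre-clustering at a 0.05 genetic distance cutoff,
    MIMAG-style quality tiering, rank-sum representative selection,
    fragment-based average nucleotide identity (ANIb-style) with
    aligned-coverage filtering, complete-linkage refinement at the 95% ANI
    species boundary, and conversion of normalized contig depths into SGB
    relative-abundance profiles. A synthetic-community simulator with
    planted ground truth (known strain divergences, MAG degradation and
    mixture weights) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan,
    withr
biocViews: Metagenomics, Microbiome, Clustering, Sequencing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
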