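Package: tastkit
Title: Long-Read Transcript Alignment Visualization and Tandem-Repeat
    Analysis for Genomic Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring gene loci with long-read RNA sequencing and
    high-accuracy genomic contigs (e.g. BAC clones). Chains local BLAST
    alignments of full-length transcripts into ordered, ORF-annotated,
    collinearity-flagged alignment structures and renders them; profiles
    tandem-repeat architecture by self-alignment depth and clusters repeat
    monomers by k-mer composition (PCA plus DBSCAN); computes a merged-interval
    pairwise identity statistic T = I/L from collections of local alignments;
    preprocesses long reads (quality filtering, two-ended barcode
    demultiplexing, poly-A orientation, N50); and mines transcript sets for
    cysteine-rich open reading frames such as metallothioneins, with tissue
    count summaries, 3'-UTR clade classification and IUPAC splice-site
    consensus. Includes a seeded synthetic-locus and read simulator and a
    naive seed-and-extend local aligner so every analysis is testable without
    external aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
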