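Package: bzipkit
Title: Characterization of Plant bZIP Transcription Factor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize basic leucine zipper (bZIP) transcription
    factor families from protein sequences and gene models: detection of the
    bZIP domain via the invariant N-x7-R/K basic-region motif and its leucine
    heptad zipper, classification of DNA-binding-site variants at the -18/-10
    specificity positions, mapping of intron splicing phases (P0/P1/P2) onto
    the basic and hinge regions with pattern classification, heptad-register
    assignment and dimerization-property statistics (a/d/e/g composition,
    Asn-at-a histograms, g-e' electrostatic pair classes), tandem-duplication
    cluster detection, Nei-Gojobori Ka/Ks estimation with Jukes-Cantor
    correction and binned Ks distributions, and expression profiling of
    seed-development FPKM matrices and 2^-ddCt qPCR time courses. A
    synthetic-data generator produces bZIP-like proteins, gene models,
    diverged codon pairs, gene-order tables and expression data with known
    ground truth so every pipeline stage is testable without genome
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
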