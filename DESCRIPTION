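Package: tnseqr
Title: Gene Essentiality from Transposon Insertion Sequencing in Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of TA-targeting transposon insertion sequencing
    (Tn-seq) experiments in yeast. Indexes TA dinucleotide target sites
    from a genome FASTA and GFF3 annotation, converts transposon-genome
    junction reads into unique insertion-site libraries (trimming,
    unique ungapped mapping, TA-site calling), computes per-gene
    insertion statistics including the Gene Insertion Index, fits a
    two-feature logistic regression returning a non-essentiality
    probability per gene, classifies genes into four essentiality
    categories, provides insertional-bias diagnostics (region fractions,
    segment profiles, sequence logos, saturation curves), compares
    essentiality calls between growth conditions, and simulates genomes,
    insertion libraries and junction reads with known ground truth for
    validation.
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
    Rsamtools,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    methods
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
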