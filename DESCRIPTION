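Package: alienscan
Title: Phylogenomic Screening for Horizontal Gene Transfer and Outlier
    Chromosome Architecture in Picoeukaryote Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting horizontally transferred genes from
    bootstrap-annotated gene trees via nearest-neighbor clade taxonomy,
    screening BLAST-tabular homolog hits with a top-score retention rule,
    profiling chromosomes by windowed GC content to find and delineate
    low-GC outlier chromosomes, scanning for physical clusters of
    expressed or intron-rich genes with exact hypergeometric tests, and
    computing comparative gene-family statistics (pan/core curves, family
    expansions, GO term enrichment). A synthetic-genome generator with
    planted ground truth (outlier chromosomes, small AT-rich introns,
    transfer events) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
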