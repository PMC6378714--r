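Package: lincscreen
Title: Intergenic lncRNA Annotation and Automated Phenotyping for C. elegans Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of the computational arms of a Caenorhabditis
    elegans long intergenic non-coding RNA (lincRNA) screen. The annotation arm
    filters and merges de novo transcript models into intergenic lncRNA loci
    (size, coding-potential and gene-distance filters), orients mono-exonic loci
    with CAGE tag clusters, profiles GC content and nucleotide conservation, and
    tests genomic-interval enrichment against chromatin annotations by
    permutation. The phenotyping arm analyses automated-microscopy recordings:
    movement-based animal counting from difference images, multi-animal tracking
    by Hungarian assignment, windowed growth-curve estimation, and brood-size and
    knockout-versus-RNAi effect statistics. A synthetic-data module generates
    every input the pipeline consumes from a seed, so all stages run and are
    tested without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    EBImage,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
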