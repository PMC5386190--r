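Package: dualtx
Title: Double-Comparative dRNA-Seq Primary Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of bacterial primary
    transcriptomes from differential RNA-seq (dRNA-seq) data. Implements
    library scaling and library-specific correction factors, calling of
    true primary positions (transcription start sites, TSSs), coverage-based
    segmentation of transcriptional units (TUs) and their classification
    into gene-covering, antisense, internal and free-standing classes,
    5'/3' UTR and leaderless-mRNA annotation, the unique expression factor
    (UEF) statistic with a Gamma-Poisson significance test, cross-strain
    TSS conservation for every class (including a built-in seed-and-extend
    nucleotide aligner with Karlin-Altschul E-values), promoter -10-element
    divergence scanning, and detection of actuatons (abundant discrete
    sRNAs that read through into a downstream gene lacking its own gTSS).
    Ships a synthetic two-strain data generator with planted ground truth
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
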