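Package: devstab
Title: Developmental Stability and Evolutionary Conservation of Embryonic
    Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies developmental stability of whole-embryo
    transcriptomes from genetically matched twin pairs, separates
    biological from technical expression variation with a rank-based
    filter against technical quadruplicates, corrects per-gene expression
    variation for its expression-level dependence with a running-median
    procedure, and relates gene expression stability to micro- and
    macroevolutionary conservation, pleiotropy, GO-slim enrichment and
    regulatory-sequence features (ATAC peak assignment, substitutions in
    open chromatin, TATA-box counts). Ships a synthetic-data generator
    that emulates the twin-pair study design (stage-specific noise,
    technical quadruplicates, population divergence, a toy genome) so the
    whole pipeline is testable without sequencing data, and rank-based
    stage comparisons (Kruskal-Wallis followed by Steel-Dwass all-pairs
    multiple comparisons).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
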