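Package: varepi
Title: Integrative Annotation of Genomic Variants at Epigenetically
    Stable Regulatory Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for interpreting genomic variants
    called between paired cell states (for example a pluripotent stem
    cell line and its induced derivative). Variants are classified into
    genomic region categories with per-category fold enrichment,
    assigned to their nearest transcription start site, and cross-
    referenced with histone-mark peak calls to identify variants whose
    local epigenetic state (H3K4me3 promoter or H3K27ac enhancer
    activity) is stable across the two conditions. Differential
    expression of the assigned genes and allele-aware position weight
    matrix rescoring of transcription-factor binding sites then single
    out candidate variants that plausibly act on expression by altering
    transcription-factor binding affinity rather than through
    epigenetic change. A fully self-contained synthetic-data generator
    with a planted truth manifest exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
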