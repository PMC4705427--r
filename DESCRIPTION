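Package: peaksig
Title: Peak Grouping and Target-Gene Signatures for Inducible
    Transcription-Factor ChIP-Seq
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of two-condition ChIP-Seq and expression
    data for an inducible transcription factor. Merges peak calls across
    conditions, scores length- and depth-normalised read coverage per merged
    region, classifies regions into functional groups from transcription
    factor and H3K27ac fold changes, assigns regions to genes by
    promoter/intragenic/intergenic rules, intersects group genes with
    up-regulated genes to derive a high-confidence target-gene signature,
    quantifies co-binding between peak sets, and stratifies expression
    datasets by correlation-based hierarchical clustering on the signature
    with bootstrap node support. Includes a synthetic-data module that
    generates annotation, peaks, reads and expression matrices with planted,
    recorded ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    ape,
    limma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
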