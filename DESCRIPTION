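Package: methylink
Title: Threshold-Based DMR Calling and Methylation-Expression Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multiomics integration toolkit for tumor methylome studies built
    around targeted bisulfite sequencing. Computes per-CpG methylation ratios
    from Bismark-style cytosine reports with both-strand collapsing, calls
    differentially methylated regions (DMRs) by tumor-vs-normal mean-ratio
    thresholds, scores and ranks differentially expressed genes by their DMR
    fraction, detects tumor-class-specific probes against a reference
    methylation-array cohort, embeds cohorts with t-SNE on the most variable
    probes, and quantifies the methylation-expression relationship per probe
    with ordinary least-squares linear models. Also implements bespoke
    filtering rules for annotated variants (depth, population-frequency and
    region filters), tumor mutation burden, copy-number log2-ratio threshold
    calling with ZRPKM normalization, and gene-fusion candidate filtering.
    A fully seeded synthetic-data generator plants ground truth at every
    stage so the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rtsne,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
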