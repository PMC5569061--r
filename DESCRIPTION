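Package: mirnaomekit
Title: Small RNA-Seq miRNA Discovery Post-Processing and miRNAome
    Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing and characterization of a species miRNAome from
    small RNA sequencing discovery output. Given miRNA-discovery candidate
    tables, per-sample read stacks and tabular alignment hits, the package
    filters candidates by a signal-to-noise score threshold, expression and
    repetitive/structural-RNA screens, calls conservation and assigns
    miRBase-style families and names, summarizes 5p/3p arm usage and detects
    arm switching across tissues, detects genomic miRNA clusters (inter-gene
    distance below 10 kb on one strand), classifies reads into the isomiR
    taxonomy (templated, non-templated, polymorphic), and scans UTR sequences
    for canonical seed sites (6mer, 7mer-A1, 7mer-m8, 8mer). A synthetic-data
    module generates every pipeline input with planted ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    withr,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
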