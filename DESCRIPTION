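Package: clonalswitch
Title: Clonal Barcode Tracking, Enhancer Switching and Amplicon Variant
    Filtering for Non-Genetic Drug Resistance
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying stable non-genetic drug resistance in
    leukaemia models. Implements extraction, validation and exact-match
    quantification of semi-random lineage barcodes (repeating IUPAC unit
    NNSWSNNWSW behind a fixed constant region) from amplicon FASTQ,
    serial-replating retention analysis of clonal barcodes under drug
    escalation, rule-based classification of newly formed versus
    pre-existing enhancers from per-condition chromatin coverage with
    TSS-window gene linking, summit-centred coverage metaprofiles,
    quantification of coactivator redistribution between enhancer
    classes, and targeted-amplicon variant filtering with duplicate
    concordance and cohort-level exclusions. A synthetic-data module
    generates every input with known ground truth: degenerate barcode
    reference libraries, clone abundance trajectories under serial
    replating with drug escalation, barcode amplicon reads, genomic
    fixtures with planted enhancer classes, and cohort variant tables
    with planted artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    GenomeInfoDb,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, Epigenetics, FunctionalGenomics, Software
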