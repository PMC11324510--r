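Package: editscreen
Title: Base Editor Screen Design and Single-Cell Long-Read Genotype-Phenotype Integration
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Designs CRISPR base-editor guide RNAs for requested amino-acid
    substitutions and enumerates all achievable editing-window outcomes
    (bystander and byproduct edits included); genotypes engineered mutations
    per cell from aligned long reads of a target transcript via soft-clip
    barcode/UMI extraction, edit-distance UMI consolidation and per-UMI
    plurality consensus; validates long-read genotypes against short-read
    amplicon evidence; and integrates per-cell genotypes with sparse
    single-cell expression matrices to classify each variant as
    wild-type-like or functionally significant from cluster-proportion
    profiles and pathway module scores. Includes a fully synthetic,
    truth-annotated data generator covering every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    rtracklayer,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
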