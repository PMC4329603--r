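Package: ASAFindR
Title: Prediction of Nucleus-Encoded Plastid Proteins in Algae with
    Secondary Plastids of the Red Lineage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies nucleus-encoded, plastid-targeted proteins in
    diatoms and other algae with secondary plastids of the red lineage
    from protein sequences and external signal-peptide predictions.
    Builds information-weighted scoring matrices for the conserved
    "ASAFAP" cleavage-site motif, relocates signal-peptide cleavage
    sites within a five-position sliding window, scores transit
    peptides, and assigns one of four confidence classes. Includes
    confusion-matrix evaluation statistics (sensitivity, specificity,
    Matthews correlation coefficient, ROC points), a toy-scale gene
    catalog optimizer (in-frame ORF extension, validity filters,
    per-locus selection, identity-based rescue of unmapped models), a
    seeded synthetic-data generator for benchmarking, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
biocViews: Software, SequenceAnalysis, Classification
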