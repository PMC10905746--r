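Package: calenh
Title: Spike-In Calibrated Occupancy Analysis and Enhancer Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spike-in calibrated CUT&Tag/CUT&RUN occupancy
    data in a differentiation time course. Provides genomic interval arithmetic
    (intersect, merge, closest, TSS windows), fragment counting and RPKM/CPM
    normalization, exogenous-genome spike-in scaling factors, a local-background
    Poisson broad-peak caller, a sum-conditional negative-binomial exact test
    with Benjamini-Hochberg FDR and independent filtering, a classification
    ladder from validated peaks through promoter/enhancer annotation,
    super-enhancer calling by the rank-curve tangent rule, 50 kb target-gene
    assignment and stem/early/late osteogenic temporal classes, transcription
    factor co-occupancy statistics (Fisher exact, Student t), PWM motif scanning
    and enrichment, and a seeded synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges
Config/testthat/edition: 3
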