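Package: aromaBSA
Title: Microarray-Assisted Bulked Segregant Analysis for Fruit Aroma Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Marker discovery for polygenic fruit aroma traits by bulked
    segregant analysis (BSA) on a subtracted diversity array. Quantifies
    volatile compounds from GC-MS peak tables by area normalisation, builds
    extreme high/low DNA bulks from an F1 segregating population, and screens
    feature signal-to-noise matrices with a from-scratch stepwise discriminant
    function analysis (Wilks' lambda selection, Fisher classification
    functions, leave-one-out cross-validation), Fisher's-ratio ranking and
    two-sample t-tests from summary statistics. Candidate markers at the
    three-criterion intersection are anchored to a reference genome through
    BLAST-style hit tables, genes are looked up within centiMorgan-derived
    physical windows, and parental amplicon SNPs are scored for
    genotype-phenotype concordance. A seeded synthetic-data generator with
    planted ground truth makes the whole pipeline testable without array
    hybridisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
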