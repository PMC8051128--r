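Package: pooltruth
Title: Construction and Verification of Pooled Multi-Cell-Line Genomic
    Reference Truth Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and verifying somatic reference truth sets
    from a pool of cancer cell lines: consensus target region construction
    from enrichment-kit designs, coding, high-confidence and low-complexity
    intervals; majority-vote consensus calling of Class 1 and Class 2
    positive variants across pipeline-library combinations; pileup-based
    calling of known-negative (homozygous-reference) positions; expected
    variant-allele-frequency arithmetic for DNA-mass pools and dilution
    series; cell-line mixture-proportion regression and cross-contamination
    detection; and droplet digital PCR Poisson occupancy modelling for
    orthogonal verification. A seeded synthetic cohort generator emulates a
    ten-cancer-line plus normal-line study design (germline sharing, copy
    number alterations, a tetraploid line, a deliberate cross-line
    contamination, replicate libraries, dilution samples and ddPCR wells)
    with full ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
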