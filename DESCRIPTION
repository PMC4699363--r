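Package: tadscape
Title: Integrative Epigenome and Chromosome Topology Analysis for
    Histone-H1-Depleted Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential analysis of DNA methylation (HpaII/MspI
    restriction-based scoring with exact binomial tests), DNase
    hypersensitivity and histone-mark ChIP signal (pooled conditional
    count tests with FDR control), enrichment statistics over
    topologically associating domains (quintile binning, enrichment
    ratios, chi-squared non-uniformity tests), and Hi-C topology
    metrics (matrix balancing, A/B compartment eigenvectors,
    distance-decay curves, paired-anchor aggregation, per-TAD domain
    scores and their differential comparison). Includes a synthetic
    two-condition data generator that plants each effect with known
    truth so every estimator can be validated by parameter recovery,
    plus a pipeline driver and plain-text readers and writers for BED,
    contact-matrix and count-table formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
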