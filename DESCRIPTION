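Package: refstab
Title: Reference Gene Selection for RT-qPCR by Multi-Method Stability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage selection of stable reference (housekeeping) genes for
    RT-qPCR normalization. Stage one screens microarray expression matrices
    with an outlier-robust 95th/5th percentile ratio of log expression and
    intersects the top-K most stable probesets across datasets. Stage two
    scores candidate genes on replicated Ct data with four stability
    measures: the comparative delta-Ct method, geNorm M-values with stepwise
    exclusion, a NormFinder-style variance decomposition with intergroup
    variation, and Haller equivalence-test fold-change intervals. Whole
    reference-gene sets can be scored as single "quasi-genes" with a
    geometric-mean efficiency and a derived Ct, and a consensus step combines
    the four rankings into a final set. A seeded synthetic-data generator
    produces Ct tables, dilution series and microarray collections with
    known ground truth so the entire pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
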