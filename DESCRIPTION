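Package: mitocov
Title: Strand-Resolved Coverage Bias and Heteroplasmy QC for
    Mitochondrial Resequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quality control of massively parallel resequencing
    of the human mitochondrial genome. Computes strand-resolved read depth
    and relative coverage on a circular reference, coverage-fraction
    threshold tables, two-letter base-class (e.g. AC, CT) composition in
    fixed-width bins and the associated coverage-bias curves, a
    sequencing-error baseline with a heteroplasmy detection-threshold
    policy, and concordance/heteroplasmy summaries of variant call sets
    against a truth panel. A synthetic-data generator simulates
    strand-biased, error-bearing, heteroplasmic pileups with a truth
    manifest so the full analysis is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
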