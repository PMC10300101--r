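Package: panelsift
Title: Tumor-Only Somatic Variant Filtering for Large Targeted cfDNA Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filters false-positive and germline variant calls from large
    targeted cell-free DNA (cfDNA) amplicon panels without matched normal
    DNA. Implements basic call filtering of UMI-consensus VCFs, extraction
    of a 22-dimensional feature vector per call (16 variant-call quality
    features plus 6 sequence-context features), a support-vector-machine
    classifier trained against hotspot-panel ground truth with nested
    leave-one-patient-out cross-validation, an exhaustive rule-based
    coverage/VAF/quality baseline, a four-component beta-mixture model of
    variant allele frequencies for germline genotyping, a consequence /
    cohort-membership / dbSNP post-processing cascade, a matched-germline
    subtraction comparator, and a Bayesian no-intercept regression on
    logit-VAFs for cross-panel concordance. A seeded synthetic-cohort
    generator makes the whole pipeline testable end-to-end offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    vcfR,
    Biostrings,
    rjags,
    coda,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
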