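Package: plasmatrace
Title: Tumor-Informed Circulating Tumor DNA Detection and Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tumor-informed liquid-biopsy analysis of plasma cell-free
    DNA: UMI/duplex read-family consensus calling of rare variants with
    background-noise and germline filtering at a 0.5% limit of detection, the
    matched-germline somatic SNV/indel filter cascade for tumor tissue, per-patient
    tissue/plasma variant partitioning with tracing fractions and maximal VAF,
    cancer cell fraction estimation with clonal/subclonal classification, and
    cohort-level statistics (contingency tests, gene-frequency correlation,
    univariate/multivariate logistic models of ctDNA detectability, one-way
    ANOVA, and CNV-vs-IHC concordance metrics). Includes a seeded synthetic-cohort
    generator emulating a primary breast cancer study population so the whole
    pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Rsamtools,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
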