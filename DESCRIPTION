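Package: mmpatterns
Title: Mining Multimorbidity Patterns from Stratified EHR Diagnosis Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers multimorbidity patterns (co-occurring chronic
    conditions) in electronic-health-record style diagnosis data. Builds an
    analysis cohort from demographics and long-format ICD-10-CM diagnosis
    tables, aggregates codes to 3-character parental categories, stratifies
    patients by race/ethnicity, age band and obesity class, mines frequent
    itemsets per stratum with an FP-growth implementation, classifies
    patterns as shared by all, some, or a single race group, and attaches
    exact binomial confidence intervals, g-tests of independence and
    tie-corrected Kruskal-Wallis tests. Ships a synthetic EHR generator
    with planted disease clusters so every pipeline stage is testable
    without access to proprietary warehouse data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
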