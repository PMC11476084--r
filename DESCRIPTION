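Package: carrierprev
Title: Germline Variant Classification and Population Carrier Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies germline variants into the five ACMG/AMP tiers with a
    loss-of-function (PVS1) decision tree, calibrated computational evidence
    (REVEL, SpliceAI) and population-frequency evidence, cross-references
    ClinVar-style and HGMD-style assertion tables, and estimates
    population-stratified carrier prevalence of pathogenic and likely
    pathogenic alleles under Hardy-Weinberg equilibrium with exact binomial
    confidence intervals. Ships a synthetic-data generator and fixtures that
    emulate gnomAD-, KOVA- and KRGDB-style allele-count tables for the
    hereditary cancer gene PALB2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    stats,
    tibble,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
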