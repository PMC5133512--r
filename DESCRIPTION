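Package: famgxe
Title: Family-Based Gene-Medication Interaction Models for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of gene-environment (gene-medication)
    interactions on quantitative traits in extended pedigrees. Provides a
    family-data simulator (gene dropping, polygenic random effects, medication
    assignment, systolic-blood-pressure-like phenotypes), pedigree numerator
    relationship matrices, founder-based principal components with projection
    to relatives, REML linear mixed models with medication-specific residual
    variances, two complementary interaction tests (a single-model
    SNP-by-medication Wald test with 1 and 2 degree-of-freedom versions, and a
    medication-stratified effect-difference test corrected for between-strata
    correlation), and true-/false-positive-proportion evaluation with an
    analytic power calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    jsonlite
Config/testthat/edition: 3
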