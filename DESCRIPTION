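Package: pgxehr
Title: Pharmacogenetic Drug-Response Phenotypes from Longitudinal EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive cardiometabolic drug-response phenotypes from
    longitudinal electronic health record (EHR) prescription and biomarker
    tables and to analyse their genetics. Includes a synthetic-EHR generator
    built on a longitudinal biomarker model with baseline-genetic,
    environmental, gene-environment and pharmacogenetic components; a
    stringent/lenient quality-control cascade with a per-step exclusion
    ledger; covariate-adjusted per-variant and rare-variant burden
    association on absolute and log-relative change scales; closed-form
    theory and simulation-based verification of the bias induced by baseline
    adjustment of change scores; non-centrality-parameter power analysis
    across allele frequencies; and polygenic-score drug-response association
    with variance-explained accounting and stratified prediction grids.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
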