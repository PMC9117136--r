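Package: prsassay
Title: Clinical Polygenic Risk Score Assay with Population-Structure Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for running a clinical polygenic risk score (PRS) assay on
    individual genotyped samples. Computes raw PRS from published weight tables
    and VCF genotypes or imputed dosages, adjusts for population structure by
    projecting samples onto reference-panel principal components and
    residualizing against a control-fitted linear model, classifies samples as
    high versus average polygenic risk using per-standard-deviation odds-ratio
    thresholds (tau = ln(target OR)/ln(OR per SD)), screens annotated variants
    for actionable secondary findings, and provides the validation statistics
    used to benchmark such an assay (Woolf odds-ratio confidence intervals,
    quantile log-odds curves, Matthews correlation, variant-site concordance).
    Includes a seedable Balding-Nichols multi-subpopulation cohort simulator so
    the whole pipeline can be exercised without access to restricted cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
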