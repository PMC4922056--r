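Package: lipidmr
Title: Stepwise Mendelian Randomization of Blood Lipids and DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to infer the causal direction between blood lipid levels
    (triglycerides, LDL cholesterol, HDL cholesterol) and whole-blood DNA
    methylation using a stepwise Mendelian randomization framework: covariate-
    adjusted epigenome-wide association with genomic control and fixed-effect
    meta-analysis across cohorts, weighted polygenic-score instruments with
    validity diagnostics, forward and reverse two-stage least-squares MR,
    cis meQTL checks for direct genetic effects, multivariable MR and Egger
    regression for pleiotropy, and a tick/cross adjudication of the steps.
    Includes a multi-cohort synthetic data generator with a configurable
    causal topology, a partial-least-squares white-blood-cell predictor, and
    methylation-expression cis association.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
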