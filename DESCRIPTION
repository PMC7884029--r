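Package: centproteo
Title: Serum Proteome Signatures of Centenarians, Survival and Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for aptamer-based serum proteomics of
    extreme-longevity cohorts. Provides covariate-adjusted differential
    abundance testing across centenarians, their offspring and age-matched
    controls with Benjamini-Hochberg control, survival-dichotomized biomarker
    signatures, cross-study significance-tier concordance classification and
    Stouffer meta-analysis, Fisher-exact gene-set over-representation
    (Hallmark, SASP), per-sample pathway projection scores, and weighted
    co-expression module networks with eigengenes. A synthetic-cohort
    generator with a ground-truth ledger supports calibration and recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
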