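Package: radresponse
Title: Radiological Response Criteria, Tumour Growth Kinetics and
    PFS/OS Surrogacy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing radiological response in slow-growing
    solid tumours followed by serial CT. Classifies tumour response per
    RECIST v1.1 and Choi criteria from longitudinal target-lesion
    diameter and attenuation series, computes growth and attenuation
    kinetics (TG, TGR, DVR, AVR), derives criterion-specific
    progression-free survival and overall survival, and evaluates
    surrogacy via Clayton-copula Kendall's tau for censored bivariate
    survival, landmark conditional survival, Mantel-Byar tests and
    time-dependent Cox models. Ships a synthetic cohort generator with
    the statistical structure these analyses assume, so the full
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tools,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
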