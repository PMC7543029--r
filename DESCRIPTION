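Package: netmma
Title: Multi-Model Inference for Population Cancer Net Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts and projects population cancer net survival by
    multi-model inference. Fits flexible parametric excess hazard models
    with restricted cubic spline baselines, non-linear and time-dependent
    covariate effects; runs an information-criterion stepwise search that
    retains every model within 2 of the minimum AIC or BIC; combines the
    retained models by Akaike/Schwarz weights with an unconditional
    variance; provides cohort and period Pohar-Perme reference estimators
    with inverse-probability-of-censoring weights, root mean integrated
    square difference (RMISD) evaluation of predictions, and a synthetic
    cancer-registry cohort generator with known true net survival.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
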