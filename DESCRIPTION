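Package: isowue
Title: Isotope-Derived Water-Use Efficiency Along Elevational Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deriving intrinsic water-use efficiency (iWUE) of C3
    and C4 grassland plants from leaf carbon isotope composition, and for
    analysing its elevational patterns and drivers. Implements the carbon
    isotope discrimination equation chain (delta-13C to Delta-13C to Ci or
    Cc to iWUE) with elevation-dependent barometric pressure and a
    temperature- and pressure-corrected CO2 compensation point, in four
    formulations (simple, photorespiratory, mesophyll, and a C4
    bundle-sheath leakiness model); a seeded synthetic transect generator
    with known ground truth; community diversity and community-weighted
    mean covariates; linear mixed-effects trend estimation with marginal
    and conditional R-squared; and multi-factor driver attribution via
    iterative VIF screening, gradient-boosted trees, and SHAP values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    knitr
Config/testthat/edition: 3
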