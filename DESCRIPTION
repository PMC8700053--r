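Package: ecdml
Title: Double Machine Learning for Early Childhood Development Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the effects of child stature and maternal
    education on early childhood development (ECD) outcomes from
    MICS-style child-level survey data. Implements UNICEF ECD index
    scoring from the ten child-development items, conventional ("ad-hoc")
    linear and logistic benchmark regressions with a small fixed control
    set, and a cross-fit partialling-out double machine learning (DML)
    engine for partially linear and logistic-partially-linear models with
    LASSO-based selection of controls from a high-dimensional candidate
    set. Includes a synthetic data generator with known causal structure
    (sparse high-dimensional confounding, two correlated treatments,
    item-level ECD responses, an age-dependent growth-faltering
    height-for-age profile) so that every stage of the analysis is
    testable without survey microdata, plus a config-driven pipeline that
    contrasts ad-hoc and DML estimates across outcome, subgroup and
    age-band grids and computes smoothed growth-faltering profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    sandwich,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
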