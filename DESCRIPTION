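Package: oilmarkr
Title: Metabolomic Marker Discovery and Authentication of Cold-Pressed Seed Oils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An untargeted LC-QTOF-MS workflow for discovering species-specific
    metabolomic markers in cold-pressed seed oils (sunflower, rapeseed, sesame,
    flax) and using them to authenticate oils and detect low-level adulteration.
    Provides feature alignment with combined relative and absolute retention-time
    and mass tolerance windows, flag/frequency/blank filtering, Pareto scaling,
    NIPALS principal component analysis, orthogonal partial least-squares
    discriminant analysis (OPLS-DA) with cross-validation and permutation
    testing, contribution-based marker selection against a negative species
    panel, targeted screening of unknown samples against a packaged marker
    library, mixture detection-limit evaluation, and bioactivity assay
    statistics (ABTS/TEAC, total phenolics, total carotenoids) with one-way
    ANOVA, Tukey HSD and compact letter displays. A synthetic-data module
    generates feature tables and assay plates with the statistical structure
    the analysis assumes, so the whole pipeline is testable without instrument
    data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
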