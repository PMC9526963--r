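Package: medpower321
Title: Monte Carlo Power Analysis for 3-2-1 Multilevel Mediation Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning cluster-randomized implementation trials that
    test mediation in three-level designs where the independent variable is
    assigned at the highest level (e.g., organization), the mediator is
    measured at the intermediate level (e.g., provider), and the outcome at
    the lowest level (e.g., patient). Designs are specified on a standardized
    scale (path coefficients plus intraclass correlations), mapped to the raw
    coefficients and variance components of a three-level Gaussian
    random-intercept model, and simulated. The indirect effect is estimated
    either by conventional multilevel regression on manifest variables with
    centered-within-context decomposition of the mediator, or by a
    method-of-moments latent between/within decomposition with cluster
    bootstrap standard errors, and tested with the first-order delta (Sobel)
    statistic. A power engine sweeps full design grids, summarizes adequacy
    by design characteristic, and searches for minimum sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
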