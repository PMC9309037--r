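Package: levelsim
Title: Fixed Versus Random Effects for Grouping Variables with Few Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying the statistical consequences of
    modelling a grouping variable with few levels (two to eight) as a fixed or
    a random effect. Generates unbalanced hierarchical Gaussian data (random
    intercepts, or random intercepts and slopes), fits linear mixed models by
    profiled restricted maximum likelihood with Satterthwaite-approximated
    tests and singular-fit detection, fits the fixed-effects alternatives with
    a coefficient-covariance bootstrap for the population-level slope, and
    estimates empirical type I error rates, statistical power, singular-fit
    fractions and variance-component distributions across study designs,
    including a random study-design sweep summarised by penalized additive
    quantile regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    lme4,
    lmerTest,
    optparse,
    purrr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
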