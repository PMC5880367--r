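Package: blicketlca
Title: Latent Class Analysis of Children's Causal-Inference Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits binary-response latent class (Bernoulli mixture) models to
    children's success patterns on blicket-detector causal-inference trials,
    with an optional age covariate on the class-membership probabilities
    (concomitant-variable model) or on the response probabilities. Provides
    EM fitting with multiple random restarts, boundary-adjusted effective
    parameter counts, BIC/AIC model selection, likelihood-ratio tests for
    nested covariate comparisons, a pattern-frequency G-squared statistic
    with a parametric-bootstrap p-value, a synthetic-data generator that
    emulates the three-strategy study design, trial scoring and item
    variability screening, 2x2 contingency comparisons (Pearson chi-square
    and Fisher's exact test), and the four-step strategy-variability
    analysis pipeline.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
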