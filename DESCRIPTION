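Package: agmtp
Title: Adaptive Graph-Based Multiple Testing Procedures for Two-Stage Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-based multiple testing procedures for confirmatory
    clinical trials with mid-trial adaptations. Implements closed weighted
    Bonferroni tests defined by directed weighted hypothesis graphs, their
    sequentially rejective shortcut, partial conditional error rates for
    preplanned one-sided z-tests and inverse-normal combination tests, and
    the adaptive closed test (agMTP) that preserves strong familywise error
    rate control under treatment-arm dropping, sample-size reallocation and
    interim changes of the weighting strategy. Also provides the simple
    adaptive comparator (saMTP / graph-based partitioning algorithm) and a
    Monte Carlo trial simulator for operating characteristics and
    sample-size determination in multi-arm two-stage designs.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
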