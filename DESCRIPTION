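Package: geneage
Title: Evolutionary Age Distributions of Gene Classes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the evolutionary age distributions of gene
    classes along a linear species timeline (phylostratigraphy). Builds
    per-class cumulative origination curves and interpolated median ages,
    compares classes with Kolmogorov-Smirnov distances and two-sample tests,
    clusters classes by complete linkage with bootstrap clade support, tests
    stochastic ordering ("stochastically younger") of class ages with
    covariance-adjusted simultaneous confidence bands calibrated by
    Monte-Carlo maximum-modulus quantiles of the Brownian-bridge limit, and
    analyses gene-class overlaps with contingency-table statistics. Includes
    a synthetic study generator with multinomial origination profiles so
    every stage of the pipeline can be exercised and calibrated without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
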