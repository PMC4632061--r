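Package: gslflux
Title: Flux Control Analysis of the Arabidopsis Glucosinolate Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of per-enzyme flux control coefficients for the
    branched aliphatic/indolic glucosinolate biosynthesis network of
    Arabidopsis thaliana from heterozygous-knockdown metabolite data,
    with percentile bootstrap confidence intervals. Includes a kinetic
    simulator of the branched pathway that doubles as a synthetic-data
    generator and as a metabolic-control-analysis oracle (finite-difference
    control coefficients, summation-theorem checks), a factorial-environment
    statistical battery (MANOVA with Wilks' Lambda, univariate follow-ups,
    proportional-change tables, two-way herbivory ANOVA), and a median-based
    expression meta-analysis for methyl jasmonate response.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
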