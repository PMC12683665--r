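Package: germscreen
Title: Salinity Screening of Seed Germination and Early Seedling Vigor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for screening crop accessions for salinity tolerance at
    germination and early seedling development. Fits nonparametric
    time-to-event (Turnbull) models to interval-censored germination counts,
    extracts germination-time quantiles (T50) with bootstrap standard errors,
    compares groups with generalized Wilcoxon scores and permutation tests,
    computes the classical germination indices (total germination, velocity
    coefficient, germination index, mean germination time, synchrony index,
    normality rate) and their stress tolerance indices, derives seedling
    vigor indices from morphometry, and classifies accessions by principal
    component analysis and hierarchical k-means clustering. Includes a
    configurable simulator of germination trials and seedling morphometry
    for pipeline validation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
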