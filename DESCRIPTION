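Package: fertconv
Title: Beta-Convergence of Fertility Indicators over Educational Attainment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cross-country convergence in fertility
    indicators (total fertility rate, mean age at childbearing, net
    reproduction rate) over changes in female educational attainment rather
    than over time. Builds the growth-over-education statistic from
    long-format country-year panels, trims extreme ratios with an
    interquartile-range fence, standardizes the estimation sample, and fits
    the convergence coefficient under country fixed effects with
    cluster-robust (CR1) inference. Includes a synthetic panel generator
    with known ground-truth convergence parameters for validation, and an
    analysis grid crossing fertility indicators, education measures and
    country subgroups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    lmtest,
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
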