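Package: dixonscan
Title: Spatio-Temporal Dixon Segregation Analysis of Land-Cover Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Local, spatio-temporal extension of Dixon's nearest-neighbour
    segregation index for detecting statistically significant change between
    two co-registered categorical land-cover rasters. For every grid cell a
    2x2 space-time contingency table is built inside a square moving window,
    the log-odds segregation index Saa is computed, and significance is
    assessed by Monte Carlo random labelling (z-scores, a chi-square-type C
    statistic and permutation p-values), with window enlargement as edge
    correction, data-driven window-size selection, per-cell uncertainty from
    the null ensemble, and transition-matrix accounting of area change.
    Includes a synthetic landscape generator for calibration and power
    checks, tidy accessors and ggplot2 visualisations, and a command-line
    interface.
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
    parallel,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
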