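Package: rsvstab
Title: Reliability Auditing of Repeated Google Trends Relative Search Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits the day-to-day stability of Google-Trends-style relative
    search volumes (RSVs) collected repeatedly for the same query, period and
    geography. Detects missing-series anomalies and applies exclusion rules,
    summarizes each geographic series with Gaussian statistics and
    Shapiro-Wilk normality screening, classifies all series pairs with a
    Welch-t confidence criterion to reach a dataset reliability verdict,
    tracks day-by-day Pearson/Spearman correlations against an external
    epidemic case series with percentage-increase and outlier diagnostics,
    and implements an incremental robust-collection protocol. A seeded
    synthetic-data generator with per-pull max-normalization and missingness
    injection supports testing without live downloads.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
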