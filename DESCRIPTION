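Package: ccwin
Title: Short Time-Window Case-Crossover Analysis of Daily Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-stratified case-crossover analysis of daily outcome and
    exposure series using short calendar windows. Implements conditional
    Poisson and conditional Gaussian regression with stratum nuisance
    parameters eliminated, calendar stratification schemes built from pairs
    or triples of consecutive days, two-week by day-of-week blocks, chained
    two-week blocks and year-month-day-of-week strata, the classical
    spline-adjusted time-series GLM comparator, a seasonal-confounding
    simulator with known slope, and a study harness that summarises slope
    recovery across methods and simulated scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
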