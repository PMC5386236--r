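Package: chamberflux
Title: Automated-Chamber Soil CO2 Efflux Processing and Soil-Warming
    Experiment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for processing raw multichannel automated-chamber records
    of soil CO2 efflux into quality-controlled hourly fluxes and
    treatment-level science products.  Implements closed-chamber linear and
    average-of-intervals flux estimators with the full water-vapour dilution
    correction, dead-band removal and iterative regression-based outlier
    rejection, a fit-quality usability threshold, pre-treatment chamber
    calibration for trenching-based respiration partitioning, warming-effect
    and Q10 temperature-sensitivity estimation, cross-chamber spatial
    variability summaries, and aggregation to daily and annual carbon sums.
    Includes a synthetic-campaign generator emulating a 15-chamber
    flow-through non-steady-state system (sequential 240-s closures, 10-s
    records, instrument faults) with full ground truth, so every stage of the
    pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
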