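Package: flyfx
Title: Estimation Statistics for Fly Behavioural and Metabolic Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, metric extraction and estimation statistics for a
    panel of Drosophila behavioural and metabolic assays. Generates synthetic
    raw-assay data (arena trajectories, foraging sessions with timed food
    epochs, capillary feeding readings with evaporation controls, climbing
    times, respirometry volumes and body-mass panels) with known ground-truth
    standardized effects; extracts the field-standard metrics (activity index,
    climbing index, evaporation-corrected intake, path efficiency, task
    performance, CO2 production rate, lipid content); and estimates raw mean
    differences, Hedges' g and Cliff's delta with bootstrap confidence
    intervals, pro-forma Mann-Whitney P values and magnitude labels. Includes
    a summary-statistics standardized-mean-difference module for forest-plot
    style synthesis of digitized literature data, and a pipeline orchestrator
    that renders a driver-by-metric effect matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
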