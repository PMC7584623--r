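Package: floatbloom
Title: Phytoplankton Bloom Phenology and Growth-Loss Balance from
    Biogeochemical Float Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving Southern Ocean phytoplankton biomass cycles
    from autonomous profiling-float observations: conversion of particulate
    optical backscattering to phytoplankton carbon, mixed-layer and euphotic
    depth estimation, a carbon-based photoacclimation model for division
    rates, a mixed-layer switching algorithm for the net biomass rate of
    change that is insensitive to entrainment dilution and detrainment,
    day-of-year climatologies, bloom phenology metrics (initiation,
    termination, loss maximum, magnitude), satellite-PAR and dissolved-iron
    matchup engines, a seeded synthetic float-array generator, and a
    climatological division-rate perturbation experiment with a temporally
    lagged loss rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1),
    methods
Imports:
    geosphere,
    stats,
    utils,
    zoo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
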