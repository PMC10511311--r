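Package: riverch4
Title: Upscaling Methane Emissions from Rivers and Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reach-scale pipeline for estimating diffusive and ebullitive
    methane (CH4) emissions from river networks. Derives hydraulic geometry
    and effective water-surface area from discharge, computes gas-transfer
    velocities from channel slope and velocity, models CH4 concentrations
    with monthly random-forest regressions carrying per-prediction
    uncertainty, corrects diffusive fluxes for supply limitation via a gas
    footprint-length mass balance, propagates uncertainty in gas exchange,
    concentration and river area by Monte Carlo, scales ebullitive fluxes
    from their log-log relation with diffusive fluxes, and estimates
    apparent activation energies of emissions from Boltzmann-standardized
    temperature regressions. Ships a synthetic river-network and
    observation-table generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    ranger,
    withr,
    geosphere,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
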