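Package: fvchain
Title: System Dynamics Simulation of a Smallholder Fruit-and-Vegetable
    Aggregation Value Chain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stock-and-flow simulator of a village-level fruit-and-vegetable
    (F&V) aggregation scheme feeding a large urban wholesale market and a
    small retail-oriented market, at half-day resolution. Couples Bass
    diffusion of scheme membership (extended with trust and relative-utility
    feedbacks) to seasonal horticultural production, farmer market and trader
    choice, farmgate price formation, trader entry and exit, perishable
    inventory with optional cold storage, and price-elastic retail demand.
    Includes a Monte-Carlo scenario engine over four upgrade dimensions
    (extension-led scaling, transport subsidy, cold storage, external demand
    growth), a three-dimensional producer-consumer-scheme trade-off
    classifier with core-subset extraction and conditional-probability
    profiles, a two-stage regional sensitivity analysis (multiplicative
    perturbation, LOESS constraint corridors, Kolmogorov-Smirnov screening of
    influential parameters), and a synthetic-fixture generator standing in
    for proprietary dashboard and market-price data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
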