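Package: lenstock
Title: Length-Based Stock Assessment for Data-Limited Fisheries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A length-based stock-assessment pipeline for data-limited
    fisheries such as the Northwest Pacific chub mackerel purse-seine
    fishery. Fits the allometric length-weight relationship, estimates von
    Bertalanffy growth parameters from length-frequency data by ELEFAN
    grid search, derives total mortality from the length-converted catch
    curve and natural mortality from Pauly's empirical formula, and runs a
    length-based Bayesian biomass estimation (LBB) with Metropolis-Hastings
    sampling of an equilibrium length-structure model, returning
    Beverton-Holt per-recruit reference points (Lopt, Lc-opt, B/B0,
    Bmsy/B0, B/Bmsy), length indicators, and a stock-status label. Also
    provides fishing-ground analytics (gridded catch/CPUE, catch-weighted
    gravity centers, Spearman rank correlations) and a synthetic-data
    generator for length-frequency samples, length-weight records, and
    fishing logbooks so every stage is testable without proprietary logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
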