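Package: n2oflux
Title: Bayesian Estimation of Nitrous Oxide Emission Factors from Chamber Flux Campaigns
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating cumulative nitrous oxide (N2O) fluxes and
    fertiliser emission factors (EFs) from static-chamber campaigns. Implements
    a log-normal spatial x log-normal temporal flux model fitted by
    Metropolis-within-Gibbs MCMC, the trapezoidal (linear-interpolation)
    cumulative-flux baseline, control-plot background subtraction, cross-event
    EF aggregation and method comparison, chamber concentration-series flux
    calculation, and a seeded synthetic campaign generator that emulates
    multi-site grassland fertiliser trials.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
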