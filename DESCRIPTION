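Package: fishconn
Title: Movement Networks and Environmental Drivers from Passive Acoustic
    Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning raw passive acoustic telemetry detection
    logs into movement networks and environmental inference for coastal
    fish. Covers detection quality control (linear clock-drift correction,
    false-detection screening), post-release filtering, extraction of
    between-receiver movements, residency and movement indices, weighted
    directed and undirected movement networks with weekly node-strength
    and degree series, a directed triad census over the 16 isomorphism
    classes, negative binomial and zero-inflated negative binomial mixed
    models of connectivity against sea surface temperature and other
    environmental covariates, heteroscedastic seasonal comparisons
    (Welch ANOVA with Games-Howell post hoc), and a stochastic simulator
    of a two-site fjord receiver array that generates detection logs with
    the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    glmmTMB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    car
Config/testthat/edition: 3
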