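Package: chronochimera
Title: Spore and Loner Bias Statistics for Dictyostelium Chronochimeras
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of social behavior in binary mixes of
    Dictyostelium discoideum populations harvested at different growth
    phases ("chronochimeras"): spore- and loner-bias statistics from
    two-colour count tables with fluorescent-label-bias correction via
    endpoint-constrained cubic profiles, frequency-dependent bias-profile
    fitting, evolutionary frequency-map analysis (fixed points, stability,
    cheater/cooperator classification), single-cell motility classification
    from mean-squared-displacement log-log slopes, adhesion-assay
    fractions, and a seeded synthetic-data generator (two-colour counts,
    two-class random-walk trajectories, go-or-grow aggregation simulator)
    so that the whole pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
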