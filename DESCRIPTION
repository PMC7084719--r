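Package: sociocog
Title: Agent-Based Simulation of Construction Workers' Sociocognitive Process and Unsafe Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discrete-time agent-based simulator of unsafe behavior on a
    construction site. Each worker runs a three-stage cognitive process per
    day (hazard detection, risk perception and understanding, behavior
    choice) coupled to evolving social norms perceived from coworkers,
    crew foremen, and site management through communication, safety
    training, behavior feedback, and behavioral demonstration. Provides a
    validated baseline configuration, norm-exclusion experiments, a
    cognitive-failure case classifier, and single- and paired-factor
    sweeps over management levers, with fully seeded, reproducible
    replicate runs and summary statistics (unsafe-behavior ratio, accident
    rate, near-miss to accident ratio, validation regressions and
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
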