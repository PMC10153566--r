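Package: healtheff
Title: Health Resource Allocation Efficiency via Super-Efficiency SBM,
    Malmquist Productivity and Tobit Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Frontier efficiency analysis of regional health resource
    allocation. Scores decision-making units (city-years) with the
    non-oriented slacks-based measure (SBM) of efficiency and Tone's
    super-efficiency SBM so that efficient units can be ranked; decomposes
    adjacent-period productivity change into the Malmquist total factor
    productivity index and its efficiency-change, technical-change, pure
    efficiency and scale components; reports input-redundancy and
    output-shortage projections from the optimal slacks; and regresses
    efficiency scores on contextual covariates by maximum-likelihood
    censored (Tobit) regression. Includes a seeded synthetic panel
    generator with known frontier and inefficiency structure, packaged
    score/index tables from a published provincial health-system study,
    and a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    numDeriv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
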