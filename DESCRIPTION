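Package: phasecr
Title: Phase-Type Models for Competing Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phase-type modelling of competing risks via absorbing
    continuous-time Markov chains with several absorbing states. Provides
    validated model representations (initial law, sub-generator, exit-rate
    matrix), all standard distributional functions (survival, density, hazard,
    cumulative incidence, subdensities, cause-specific hazards) computed by
    matrix exponentials or hypoexponential closed forms, rational
    Laplace-transform algebra with redundancy and degree analysis, conversion
    to and from the canonical Coxian mixture representation, constructive
    equivalence checking between representations through similarity matrices
    with unit row sums, simulation of right-censored (time, cause) data, and
    EM maximum-likelihood fitting of the canonical Coxian competing-risks
    model with an Aalen-Johansen nonparametric comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
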