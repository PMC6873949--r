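Package: mgusscreen
Title: Population Screening Models for MGUS and Progression to Multiple Myeloma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based and deterministic models of monoclonal gammopathy of
    undetermined significance (MGUS) incidence, screening, and progression to
    multiple myeloma (MM) in an age-structured population. Provides a discrete-time
    Markov chain simulated at the level of single individuals, an exactly matching
    deterministic cohort recursion, calibration of parametric demographic fixtures
    (Gompertz-Makeham life table, exponential-in-age MGUS incidence, geometric MM
    survival), and tools to evaluate screening policies: start age, screening
    interval, progression-risk reduction after detection, risk-stratified
    allocation of a fixed screening budget, lead-time bias, and competing-risk
    MM-specific mortality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
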