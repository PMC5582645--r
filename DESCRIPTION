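Package: ratetoprob
Title: Convert Transition Rates to Transition Probabilities for
    Multistate Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for converting transition-rate (intensity) matrices of
    continuous-time multistate Markov models into per-cycle
    transition-probability matrices for discrete-time cohort models, as
    used in health-economic decision analysis.  Provides a numeric
    conversion path based on the eigen-decomposition of the generator
    matrix, an independent series-summation matrix exponential used as a
    cross-checking oracle, and diagnostics for the known failure modes
    (defective generators, nearly equal eigenvalues, complex eigenvalue
    pairs, out-of-bounds probabilities).  A symbolic engine derives
    closed-form conversion formulas for a given transition structure via
    the characteristic equation, eigenvectors, and matrix inversion,
    organises them with named intermediate variables, and exports them as
    live spreadsheet formulas.  Also includes the naive per-transition
    exponential formula and the competing-risks decomposition for
    comparison, per-cycle/age-group rate schedules, Markov cohort traces,
    and probabilistic sensitivity analysis utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
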