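Package: amyloidosc
Title: Coupled Amyloid-Beta Aggregation-Inflammation Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a minimal five-variable kinetic model that couples
    nucleation-dependent amyloid-beta aggregation (primary nucleation, oligomer
    conversion, elongation, secondary nucleation) to a single inflammation level
    through a Hill-type response that modulates monomer generation and clearance.
    Provides regime presets (closed in vitro, open uncoupled, open coupled),
    stiff ODE integration with log-spaced or uniform sampling, in vitro-style
    aggregation metrics (logistic fits of fibril growth, lag times, double-log
    scaling exponents, average fibril length, oligomer transients), peak-based
    oscillation metrics (period, baseline-normalized amplitude, regime
    classification), one-dimensional and three-parameter bifurcation sweeps, and
    scaled steady-state sensitivity analysis. Results are returned as tibbles
    with tidy() and autoplot() methods so analyses compose with the tidyverse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
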