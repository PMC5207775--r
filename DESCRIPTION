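Package: asterwave
Title: Collective Growth of Microtubule Asters by Autocatalytic Nucleation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the growth of microtubule asters as a collective
    phenomenon driven by autocatalytic nucleation of short, dynamically
    unstable microtubules. Implements the closed-form analytics of the
    length-structured two-state model (net drift, critical nucleation
    rate, aster velocity, gap velocity, mean microtubule length, bulk
    plus-end density), a deterministic finite-difference solver of the
    transport equations in 1-D planar geometry with exact advection
    shifts, an event-driven stochastic simulator of single microtubules
    and branching populations that serves as a brute-force oracle for the
    analytic results, inversion routines that recover rescue and
    nucleation rates from measured aster velocities, and the measurement
    procedures used on imaging data (exponential fits to plus-end comet
    lifetimes, half-max front extraction from intensity profiles, and
    velocity fits to radius time series) together with synthetic-data
    generators that emulate them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
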