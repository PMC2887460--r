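Package: navblock
Title: Markov-State Simulation of Sodium-Channel Gating and State-Dependent Inhibitor Block
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates voltage-gated sodium-channel gating kinetics with
    continuous-time Markov state models and studies how inhibitors that
    preferentially bind fast- or slow-inactivated channel conformations behave
    in standard voltage-clamp protocols. Provides an eight-state
    Hodgkin-Huxley-like gating model extended to a sixteen-state "tetracube"
    with drug-bound states under microscopic reversibility, a multi-step
    activation (Kuo-Bean-like) model for architecture robustness checks, a
    voltage-protocol engine (steady-state fast/slow inactivation, onset of slow
    inactivation, recovery from inactivation, concentration-response),
    effectiveness statistics (Boltzmann midpoint shifts, biexponential recovery
    fits, normalized sum-of-differences, IC50), Monte Carlo parameter-robustness
    studies, and calibration of channel parameters against behavioral
    constraints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
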