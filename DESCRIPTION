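Package: bystandr
Title: Bystander-Killing Dynamics of Antibody-Drug Conjugate Payloads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for the pharmacodynamics of antibody-drug
    conjugate (ADC) payloads in mixed antigen-positive/antigen-negative
    tumors. Implements a closed three-compartment payload-exchange model
    between Ag+ cells, Ag- cells and the extracellular space (with an exact
    matrix-exponential solution), Emax-coupled tumor growth inhibition for
    the two tumor subpopulations with the bystander-killing effect
    switchable on or off, and an Erlang age-structured tumor growth
    inhibition model (linear-chain ODE reduction plus a renewal-integral
    reference solver) that captures the inhibition delay after dosing.
    Trajectories are returned as tibbles, plotted with ggplot2, and driven
    by validated scenario configurations (YAML/JSON) or a thin command-line
    wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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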