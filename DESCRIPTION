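Package: immunokpd
Title: Semi-Mechanistic K-PD Modelling of Immuno-Oncology Combinations in Cold Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for semi-mechanistic population pharmacodynamic modelling of
    antitumor response to combinations of a tumor antigen, a TLR-3 agonist and an
    anti-PD1 antibody in a non-inflamed (cold) tumor mouse model. Implements the
    kinetic-pharmacodynamic (K-PD) transit-compartment ODE model coupling drug
    signals, antigen-presenting cell activation, CD8 T-cell dynamics and
    exponential tumor growth; nonlinear mixed-effects estimation with a censored
    (M3) likelihood for below-quantification-limit tumor volumes; a virtual-trial
    generator reproducing the eight-arm preclinical study design; responder
    classification with simulation-based (numerical predictive check) diagnostics;
    and a parameter-grid exploration of response rates against CD8 and
    resistance-inhibition exposure metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
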