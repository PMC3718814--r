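Package: nirsrl
Title: Hemodynamic Desirability Decoding and Reinforcement Learning with
    Noisy Reward Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates dual-wavelength near-infrared spectroscopy (NIRS)
    recordings of frontal-lobe hemodynamic responses to desirable and
    undesirable outcomes, recovers oxy- and deoxyhemoglobin concentration
    changes via the modified Beer-Lambert law, decodes single-trial outcome
    desirability with a support-vector machine under jackknife
    cross-validation, and feeds the resulting decoding accuracy into a
    tabular SARSA(lambda) agent solving a 7x7 rake-and-pellet gridworld
    through a stochastically misclassified reward channel. Includes
    peri-event statistics (Welch's t-test per timestep), classifier window
    and feature sweeps, and the reward-accuracy robustness sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
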