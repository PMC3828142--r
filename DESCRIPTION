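Package: spheroidrt
Title: Agent-Based Tumour Spheroid Simulation of Cell-Cycle Effects in Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Off-lattice, single-cell-based simulation of three-dimensional tumour
    spheroid growth coupled to a cell-cycle-phase-specific linear-quadratic model of
    radiation response. Cells progress through G1/S/G2/M with individually sampled
    phase durations, enter quiescence under contact pressure and necrose on local
    glucose depletion; glucose and oxygen are resolved on a cubic reaction-diffusion
    grid with phase-specific uptake. The package provides radiosensitivity-enhancement
    and Shannon-entropy orderedness observables, clinical fractionation presets,
    constant-dose-rate and trigger/effector schedules, and an automatic
    enhancement-peak-triggered dosing policy, so that cell-cycle resynchronisation
    effects on fractionated radiotherapy outcomes can be simulated and compared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    Rcpp,
    readr,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
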