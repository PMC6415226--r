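Package: nanostarphase
Title: Phase Behaviour of DNA Nanostar Fluids from Wertheim Perturbation Theory
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts gas-liquid critical points and coexistence curves of
    sticky-ended DNA nanostar solutions by combining Wertheim thermodynamic
    perturbation theory with nearest-neighbor sticky-end hybridization
    thermochemistry and a reference-fluid equation of state. The reference
    (non-bonding) free energy is obtained either from a virial expansion
    (second or third order, with the third virial coefficient fitted to
    pressure-density data) or by thermodynamic integration of a tabulated
    equation of state. Includes a synthetic equation-of-state generator with
    known ground truth for parameter-recovery studies, tidy accessors for all
    fitted objects, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
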