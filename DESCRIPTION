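Package: photocycler
Title: Spectral and Kinetic Analysis of Photocyclic Visual Pigments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterising photocyclic and photoreversible visual
    pigments from UV-Vis absorption spectroscopy. Builds lambda-max
    parameterised nomogram template spectra for the dark state and the
    metarhodopsin II and III photointermediates, decomposes absorption and
    UV-induced difference spectra into non-negative state fractions,
    simulates dark/meta II/meta III photocycle kinetics under flash and
    continuous-light protocols, fits single-exponential thermal-recovery
    traces, and maps state populations to retinal isomer compositions. A
    seeded synthetic-data generator emulates the underlying experiments so
    every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
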