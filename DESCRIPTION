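Package: hyphabend
Title: Microfluidic Bending Tests for Fungal Hyphae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for microfluidic bending tests on fungal
    hyphae. Implements the series solution of pressure-driven laminar flow
    in rectangular microchannels, low-Reynolds-number drag models for a
    hypha lying on the channel floor or suspended at mid-height,
    Euler-Bernoulli inversion of measured tip deflections into bending
    stiffness, conversion to the cell-wall Young's modulus via the annular
    second moment of area, an equivalent fluidic-circuit model of the
    spore-loading step, and a seeded synthetic-data generator that emulates
    the wet-lab experiment for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    withr
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
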