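Package: staplecomp
Title: Tissue Compression Safety Analysis for Circular Anastomosis Staplers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Finite-element and closed-form analysis of intestinal tissue
    compressed between the anvil and staple cartridge of a circular
    end-to-end anastomosis stapler. Models the two-layer intestinal wall
    as an incompressible third-order Ogden hyperelastic annulus, compresses
    it quasi-statically between rigid platens (a semi-analytic uniform
    engine and an axisymmetric nonlinear finite-element engine), and
    classifies per-layer tissue state from the volumetric distribution of
    von Mises equivalent stress: fixation (0.3-0.6 MPa band exceeding 20%
    of the fixed-tissue volume) versus damage (above 0.6 MPa exceeding 5%).
    Derives safe compression distances, ratios and staple gaps for
    symmetric and asymmetric wall-thickness pairs, with mesh-convergence
    and force-compression validation experiments and a synthetic reference
    data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
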