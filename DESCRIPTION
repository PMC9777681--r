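Package: gelmech
Title: Large-Deformation Mechanics and Nonlinear Rheology of Biopolymer Gels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis pipeline for the large-deformation mechanics of
    hydrocolloid gels (for example agarose-xanthan mixtures). Converts ring-tensile
    and uniaxial-compression force-displacement records into engineering and true
    stress-strain curves, fits Johnson-Cook hardening and damage-failure models,
    integrates a strain-driven material-point tensile simulator, decomposes large
    amplitude oscillatory shear (LAOS) waveforms into odd harmonics and
    Lissajous-Bowditch loops, and performs minimal subset-based 2-D digital image
    correlation. A synthetic-data module generates force records, oscillatory
    waveforms and speckle image pairs with known ground truth so that every stage
    can be validated by round-trip recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
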