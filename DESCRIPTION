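Package: dbmi
Title: Dynamic Bacterial Morphology Imaging: Simulation, Quantification and
    Mechanism-of-Action Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-channel (membrane and nucleoid dye) time-lapse
    fluorescence microscopy of rod-shaped bacteria responding to antimicrobial
    treatment, quantifies single-cell morphology dynamics (kymograph patterns,
    cell and nucleoid length, background-corrected nucleoid intensity,
    intact/no-nucleoid/disintegrated cell-status fractions), and classifies the
    antimicrobial mechanism of action at three levels (cell-envelope group,
    five target classes, sub-classes) from the timed single-cell events via a
    rule-based decision scheme with a full per-criterion evidence trail.
    Includes 14 packaged antimicrobial response presets plus a solvent control
    so the whole pipeline is testable without real microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
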