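Package: drusenmorph
Title: Quantification of Epithelial Monolayer Adaptation to Drusen-Like
    Substrate Bulges
Version: 0.1.0
Authors@R:
    person("Felix", "Mercer", email = "fmercer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for confocal imaging experiments in which an
    epithelial monolayer (e.g. retinal pigment epithelium) grows over
    light-induced hydrogel bulges that mimic drusen.  Provides monolayer
    thickness profiling from resliced F-actin stacks, per-cell morphometrics
    (area, shape factor P/sqrt(A), orientation and angle-to-origin) from
    labelled segmentation masks, radial Top/Edge/Outside region statistics,
    swelling kinetics and illumination dosimetry, Hertz contact-model fitting
    of force-indentation curves, and traction force microscopy
    (PIV bead displacement plus regularized Fourier-transform traction
    cytometry).  A seeded synthetic-data module generates every input type
    with known ground truth so the whole pipeline is testable without
    external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
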