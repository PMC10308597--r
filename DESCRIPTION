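Package: beadpulse
Title: Multifrequency Resistive-Pulse Readout of Metallized-Bead Immunoassays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of multifrequency impedance (Coulter-type
    resistive pulse) measurements of microbeads transiting a microaperture,
    as used in electronic bead-based immunoassays where analyte binding is
    transduced into enzymatic silver metallization of the bead surface.
    Provides lumped-element circuit models of the sensing zone and of
    nonmetallized and metallized beads, a seeded waveform synthesizer,
    high-pass filtering and threshold peak detection, spectral gating of
    metallization subpopulations, a z-scored two-class linear-discriminant
    metallization metric, and four-parameter-logistic dose-response fitting
    with limit-of-detection estimation and trial classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
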