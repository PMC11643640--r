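Package: kndysim
Title: Conductance-Based Modelling of Arcuate Kisspeptin (KNDy) Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hodgkin-Huxley-style single-cell model of arcuate kisspeptin
    (Kiss1-ARH / KNDy) neurons with twelve ionic currents, single-compartment
    calcium dynamics and neurokinin-B / dynorphin receptor drives. Ships
    calibrated parameter presets for the ovariectomized (OVX) and
    estradiol-replaced (OVX+E2) hormonal states, declarative voltage- and
    current-clamp protocols (I-V step families, M-current deactivation,
    current ramps, saturating receptor drives), trace analysis (spike and
    burst detection, firing-mode classification, rheobase, F-I and I-V
    curves, Boltzmann activation/inactivation fits, drug-subtraction,
    repolarization decomposition), least-squares conductance calibration
    against printed current-density anchors, two-dimensional
    conductance-space regime scans with boundary extraction, qPCR
    delta-delta-CT quantification utilities, and seeded
    synthetic-electrophysiology generators so every analysis operator is
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
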