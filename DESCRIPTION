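Package: gabakcc2
Title: GABA-A Gating, Chloride Homeostasis and Analgesic Synergy Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying the interaction between
    GABA-A receptor function and KCC2-mediated chloride extrusion in spinal
    dorsal horn neurons. Implements a three-state GABA-A gating simulator
    driven by a synaptic GABA transient, a one-compartment anion-current /
    KCC2 pharmacodynamic model (including the high-dose collapse of the net
    inhibitory current and the two-drug combination surfaces), Hill
    dose-response and Loewe dose-equivalence / isobologram statistics, and
    the fluorescence quantification operators used for synaptic punctum
    detection, membrane-index and transcript-count analyses. Ships
    synthetic-data generators with ground-truth records so the whole
    pipeline is testable without raw recordings or images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
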