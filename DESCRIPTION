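Package: mitovasc
Title: Mitochondria-Driven Calcium Dynamics in Vascular Smooth Muscle Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Whole-cell model of free calcium handling in a cerebral vascular
    smooth muscle cell in the aftermath of cortical spreading depression,
    when calcium-phosphate stores hold the mitochondrial matrix at a fixed
    saturation concentration. The stiff ODE system couples cytosolic and
    endoplasmic-reticulum calcium (rapid-buffer approximation), IP3/PIP2
    turnover, De Young-Keizer IP3-receptor and four-state ryanodine-receptor
    gating, SERCA, the mitochondrial uniporter, NCLX and an Ohmic matrix
    leak, plasma-membrane NCX, VOCC, PMCA and leak fluxes, and a four-state
    cross-bridge (latch) model of contraction. The model is calibrated so
    the physiological resting state is an exact fixed point; tools locate
    the oscillation onset in matrix calcium, track calcium clearance and
    ATP-synthesis-equivalent fluxes, and sweep compartment flux rescalings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
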