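Package: stromasim
Title: Multiscale Simulation of Tumor-Stromal Signaling and Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A three-level simulator of tumor-stromal interaction in the
    tumor microenvironment. Intracellular TGF-beta, LIF and CXCL12
    signaling in cancer cells and cancer-associated fibroblasts (CAFs) is
    modeled as nonlinear ODE reaction networks; secreted signals diffuse
    through a 3-D spherical microenvironment by reaction-diffusion;
    individual cancer cells are classified as quiescent, proliferative or
    migratory from local signal levels and moved by a force-based
    (Hertz contact, adhesion, haptotaxis, active-force) overdamped
    mechanics layer. Unknown kinetic parameters are estimated from sparse
    expression time courses with a continuous-discrete (hybrid) unscented
    Kalman filter; Morris elementary-effects screening and standard
    goodness-of-fit and Bland-Altman statistics support model assessment.
    Synthetic-data generators produce all inputs needed to exercise and
    test the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
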