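Package: hemopoiesis
Title: Feedback-Regulated Hematopoiesis and Chronic Myeloid Leukemia
    Therapy Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A branched-lineage ordinary differential equation model of
    hematopoiesis (stem cells, multipotent progenitors, terminally
    differentiated myeloid and lymphoid cells) under nonlinear negative
    feedback and feedforward regulation of self-renewal, branching and
    division rates. Provides automated design-space model selection over
    candidate regulation architectures via dominant power-law subsystems
    (S-systems), virtual-patient cohort construction by uniform parameter
    sampling with steady-state acceptance, a dual normal/leukemic lineage
    extension for chronic myeloid leukemia, tyrosine kinase inhibitor and
    combination differentiation therapy simulation with BCR-ABL1
    transcript readout, transplant and depletion perturbation
    experiments, and ROC-based prognostic evaluation of early transcript
    dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
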