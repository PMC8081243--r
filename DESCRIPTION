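Package: fecgsim
Title: Bidomain Forward-ECG Simulation and Parameter Sensitivity on Synthetic Heart-Torso Anatomies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element forward simulation of focal ventricular excitation
    with the bidomain-with-bath equations and the ten Tusscher-Panfilov 2006
    human ventricular ionic model on labeled tetrahedral heart-torso volume
    conductors. Provides a synthetic anatomy generator (biventricular
    myocardium, blood pool, lungs, liver, spine, torso bulk) with a rule-based
    myofiber field, Laplace-Dirichlet anatomical coordinates, body-surface
    electrode vests and focal pacing sites; Roth-framework anisotropic
    conductivity tensors with transmural and apicobasal heterogeneity rules;
    derivation of body-surface maps and 12-lead electrocardiograms;
    depolarization and repolarization biomarkers; and a one-at-a-time
    sensitivity pipeline (CC, NRMSD, relative Euclidean distance, max-RED
    rankings, biomarker spans, regional sensitivity maps).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    xml2,
    tools,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
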