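Package: rotormap
Title: Rotor Mapping and Virtual Ablation in Simulated Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional monodomain simulation of human atrial tissue with
    Courtemanche-Ramirez-Nattel ionic kinetics under control and persistent-AF
    conductance remodeling, together with the analysis stack used to study
    fibrillatory drivers: phase mapping and Iyer-Gray phase-singularity
    detection, rotor-tip trajectory tracking and a quantitative mother-rotor
    classifier, per-node dominant-frequency maps, Shannon-entropy and
    complex-fractionated-electrogram cycle-length maps from virtual bipolar
    electrograms, spatial-overlap statistics between parameter areas, and four
    virtual-ablation strategies (PS-, DF-, ShEn- and CFAE-guided) with
    post-ablation outcome classification. Includes analytic spiral and
    electrogram fixture generators so every analysis stage is testable without
    running the PDE solver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
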