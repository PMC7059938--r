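Package: gjcable
Title: Gap-Junction Mediated Conduction in Cardiac Cell Strands
Version: 0.2.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multiscale simulation of electrical conduction in one-dimensional
    strands of cardiac myocytes coupled by voltage-dependent gap junctions.
    Provides the instantaneous and steady-state transjunctional conductance
    laws for Cx43/Cx45 channels, a non-Ohmic homogenized cable model whose
    effective conductivity depends on the local potential gradient, its linear
    (Ohmic) counterpart, discrete cellular circuit models resolved at the
    subcellular scale, Luo-Rudy phase-I membrane kinetics, and experiment
    drivers for conduction-velocity/coupling sweeps, retrograde conduction,
    restitution, conduction-block detection and mesh-refinement studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ggplot2,
    tibble,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
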