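Package: permion
Title: Ion Permeation Conductance and Pore Geometry from Steered-Pulling Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing pipeline for molecular-dynamics studies of
    connexin-like channels: converts steered-pulling force logs into
    potentials of mean force, estimates unitary channel conductance from a
    full-channel free-energy profile via mean-first-passage-time theory with
    a Debye-screening multi-ion correction, quantifies departure of a
    hexameric pore from six-fold symmetry (eccentricity coefficient and
    hexagon angles, compared with the Mann-Whitney U test), and detects
    rupture events in force-ramp pulling traces. Ships a synthetic-data
    generator (overdamped Langevin steering, noisy hexamer trajectories,
    force ramps with prescribed rupture forces) so every stage is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
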