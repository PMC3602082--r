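Package: cardiomech
Title: Discrete Electromechanical Modelling of Human Cardiac Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled simulation of human ventricular electrophysiology and
    tissue mechanics on a two-dimensional sheet. Excitation follows the ten
    Tusscher-Panfilov 2006 (TP06) epicardial ionic model solved with an
    explicit finite-difference monodomain scheme; active tension follows the
    Niederer-Hunter-Smith (NHS) excitation-contraction model adjusted for
    human myocytes; passive elasticity is a mass-spring lattice (Seth
    material) relaxed to elastostatic equilibrium by damped Verlet iteration
    with the length/velocity tension scalings re-evaluated inside the
    mechanical loop ("update method"); deformation feeds back on excitation
    through stretch-activated channels. Includes pacing, restitution, and
    S1-S2 spiral-wave protocols with action-potential-duration, conduction
    velocity, and spiral tip/core/drift measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
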