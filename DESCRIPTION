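Package: exowalk
Title: Simulating Ankle Exoskeleton Torque Effects on Walking Balance
Version: 0.1.0
Authors@R: person("exowalk", "maintainers", email = "exowalk@example.org",
    role = c("aut", "cre"))
Description: A reduced three-dimensional musculoskeletal walking simulator for
    studying how short bursts of ankle plantarflexion and subtalar
    inversion-eversion exoskeleton torque change whole-body center-of-mass
    kinematics and center-of-pressure position. Provides a 23
    degree-of-freedom rigid-body model with Hill-type muscle-tendon units and
    smoothed Hunt-Crossley foot-ground contact, a deterministic synthetic
    gait generator, a direct-collocation (Hermite-Simpson) tracking stage, a
    windowed forward-integration perturbation engine with muscle-driven and
    torque-driven modes, and dimensionless outcome analysis (Froude-scaled
    velocities, foot-width-scaled center of pressure, whole-body angular
    momentum).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
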