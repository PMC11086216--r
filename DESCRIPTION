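Package: emgtorque
Title: EMG-Driven Hill-Type Modelling of Ankle Joint Torque
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes ankle joint torque from surface electromyography (sEMG)
    envelopes and joint kinematics with a Hill-type muscle-tendon model of
    four lower-leg muscles (tibialis anterior, soleus, medial and lateral
    gastrocnemius). Includes activation dynamics with electromechanical
    delay, force-length / force-velocity / tendon / pennation sub-models
    with Runge-Kutta fiber-length integration, polynomial joint geometry,
    genetic-algorithm calibration of the 16 per-muscle physiological
    parameters against measured torque, a synthetic-trial generator for the
    five standard ankle movements, and an evaluation pipeline reporting
    torque RMSE and per-muscle contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
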