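Package: bicar
Title: Bimanual Cable-Driven Rehabilitation Robot Simulation and Movement Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-free computational core of a two-cable bimanual
    rehabilitation robot. Provides forward and inverse cable-length
    kinematics for the one-degree-of-freedom, planar and bimanual
    handlebar setups, discretized circular and polygonal trajectory
    generation, a force-map serious-game controller with
    assist-as-needed logic (crystal-catching game with constant,
    accelerated and dynamic difficulty modes), a closed-loop synthetic
    patient model that emulates reaction delays, hemiparetic force
    asymmetry, fragmented sub-movements and sensor quantization, and a
    movement-performance metric engine (reaction and movement times,
    angular speed, normalized jerk, velocity-peak counts, force and
    torque symmetry, RMS position error) with outlier validation,
    longitudinal progress series and group comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
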