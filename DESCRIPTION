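Package: graspsel
Title: Normative Model of Human Two-Digit Grasp Selection on 3D Objects
Version: 0.1.0
Authors@R: person("Grasp", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes per-grasp penalty maps (force closure, torque, natural
    grasp axis, grasp aperture, object visibility) over all ordered pairs of
    candidate contact points on a triangulated 3D object, combines them into
    an overall grasp cost, samples predicted optimal precision-grip grasps,
    fits per-participant constraint weights to observed grasps by bounded
    least squares, and quantifies grasp similarity and related behavioral
    statistics. Includes a polycube stimulus builder, ASCII mesh readers
    (OBJ, STL, PLY), a synthetic grasp observer for parameter recovery, and a
    command-line pipeline with model perturbation experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
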