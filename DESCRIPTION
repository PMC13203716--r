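Package: squatsim
Title: Predictive Simulation of Load-Dependent Squat Posture with
    Moment-Limited Joints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static, frame-by-frame prediction of barbell squat
    posture from a reduced rigid-segment body model.  A smooth reference
    squat trajectory is corrected at every motion frame by minimizing a
    tracking + joint-energy + gravitational objective over five
    generalized coordinates (pelvis translation and orientation, torso
    pitch), subject to kinematic reachability of both legs.  Joints are
    bounded tanh moment-rotation elements that yield and permanently
    soften once their moment approaches capacity, so increasing barbell
    load produces emergent technique adaptations: posterior pelvis shift,
    forward torso lean and redistribution of rotational demand from the
    knee toward the hip.  Includes a load-sweep driver, tidy accessors,
    ggplot2 visualisations and CSV/JSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
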