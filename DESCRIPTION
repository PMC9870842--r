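Package: tapsim
Title: Models of Tapping on Jittering and Moving Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of goal-directed tapping on laterally
    jittering, moving and accelerating targets. Generates frame-based target
    step sequences (random walks, drifting walks, graded step-size
    variability, constant-acceleration block designs), implements a
    delayed-extrapolation aiming model with leaky-integrator velocity
    accumulation, trial-to-trial spatial and temporal error-correction
    learning with forgetting, minimum-jerk and stiffening mass-spring-damper
    response models for synthetic finger trajectories, and the step-triggered
    response analysis pipeline (Savitzky-Golay kinematics, tap detection,
    step-sorted trial splitting, response curves, gain and tapping-error
    differences) used to study how humans combine instantaneous position
    information with accumulated velocity information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
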