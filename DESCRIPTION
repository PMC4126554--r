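Package: idsm
Title: Iterant Deformable Sensorimotor Medium for Simulating Habits as
    Self-Maintaining Patterns of Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a plastic, node-based dynamical controller (an
    iterant deformable sensorimotor medium) in which trajectories taken
    through sensorimotor space reinforce themselves, so that repeated
    patterns of behavior become self-maintaining habits.  Provides the
    medium itself (node creation, weight dynamics and the kernel-weighted
    motor velocity field), two simulated robot bodies (a one-dimensional
    light-following robot and a two-wheeled robot with directional light
    sensors in a periodic arena), externally imposed training controllers
    (oscillatory, circular and Braitenberg-style phototaxis/photophobia),
    random-walk initialization of the medium, a phase-scheduled experiment
    runner with relocation events and frozen flow-field probes, and
    trajectory analyses (distance-to-light statistics, lattice region
    coding, PCA projection, oscillation and recurrence estimators).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
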