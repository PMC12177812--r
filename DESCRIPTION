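Package: duelingorbits
Title: Simulation and Cue-Combination Modelling of the Dueling Orbits
    Induced-Motion Illusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying induced motion with orbiting target/inducer
    displays ("dueling orbits"). Generates the world-frame kinematics of a
    central orbiting target surrounded by four synchronously orbiting
    inducers (including the six canonical stimulus presets), simulates eye
    traces for fixation and smooth-pursuit viewing conditions, derives the
    retinal, eye-centered and relative trajectories of the target, and
    predicts the perceived trajectory as a reliability-weighted combination
    k * eye-centered + (1 - k) * relative of the two motion cues. Shape
    analytics (radial lobe count, second-moment aspect ratio and
    orientation, polyline self-intersections, side concavity) quantify the
    predicted percepts, and an inverse estimator recovers the cue weight k
    from observed percept traces, with bootstrap confidence intervals and a
    synthetic-observer generator for parameter-recovery studies. Includes
    plain-text CSV/JSON/YAML interchange, ggplot2 visualisation, and a
    command-line interface with a schematic rasterizer for the stimuli.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
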