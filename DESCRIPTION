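Package: dyadvigor
Title: Movement Vigor and Coordination in Physically Coupled Wrist Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how individual movement vigor shapes reaching
    movements of physically coupled human dyads. Provides a synthetic-data
    generator emulating solo and coupled wrist-reaching sessions, a kinematics
    pipeline (zero-phase filtering, velocity-threshold segmentation, reaction
    times, amplitude-duration regression, spectral smoothness), vigor scoring
    and variance decomposition, a linear mixed model of dyadic vigor,
    inverse-optimal-control identification of an individual cost of time from
    amplitude-duration laws via minimum-torque-change optimal control, and
    forward simulation of four dyadic coordination hypotheses (co-activity,
    leader-follower, weighted adaptation, interactive adaptation) including a
    stochastic free-final-time optimal-control model of dyadic movement
    duration under partner-timing uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    lme4,
    lmerTest,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
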