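Package: betawheel
Title: Subthalamo-Cortical Beta Dynamics During Continuous Wheel Turning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of subthalamic-cortical oscillatory
    dynamics during continuous rotational movements with starts, reversals,
    and stops under predictable versus unpredictable cueing. Provides a
    synthetic cohort generator with known ground truth (task sequences,
    wheel-encoder kinematics, coupled band-limited neural signals), rotary
    encoder kinematics and semi-automated movement event detection,
    multitaper time-frequency power and across-trial coherence with Slepian
    tapers, non-parametric spectral Granger causality via Wilson spectral
    matrix factorization with a time-reversal control, cluster-based
    permutation inference on time-frequency maps, and behavioral and
    band-summary statistics (paired tests, repeated-measures ANOVA, effect
    sizes, lateralization index), orchestrated by an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
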