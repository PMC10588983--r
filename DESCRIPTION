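Package: windnav
Title: Wind-Oriented Navigation Metrics for Walking Flies in Circular Arenas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies wind-oriented (anemotactic) locomotion of walking
    Drosophila in four-quadrant circular olfactometer arenas from per-frame
    tracked trajectories. Provides arena and stimulus-schedule bookkeeping,
    trajectory I/O and quality filters (tracking-error and arena-edge rules),
    per-frame kinematics (area-normalized radial position index, angle to
    upwind, angular velocity, forward walking speed), population navigation
    metrics (upwind displacement, mean cosine of the upwind angle,
    orientation-gated cumulative turning, return probability, quadrant
    preference index with reciprocal averaging), a z-scored multi-parameter
    activation-screen matrix with hit ranking, and an agent-based
    correlated-random-walk simulator of fly trajectories with artifact
    injection for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
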