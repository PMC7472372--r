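Package: fixmon
Title: Instrumented External Fixator Telemetry and Bone Callus Stiffness
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring bone regeneration with an instrumented
    external fixator. Implements the framed binary load-cell telemetry format
    with sync-mark resynchronization and static-rest baseline normalization,
    the bone-fixator force-partitioning model with distraction-phase (peak
    callus stiffness) and consolidation-phase (parallel-spring inversion)
    stiffness estimators, Young's modulus conversion, a GUM-style
    reference/replication/repetition uncertainty budget for spring-bench
    calibration, and a synthetic bench that simulates the fixator, callus
    viscoelasticity, gait, sensor noise and drift with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
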