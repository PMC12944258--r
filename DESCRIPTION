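Package: gaitmos
Title: Margin-of-Stability Estimation from Wearable IMU Signals via
    Principal Motion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dynamic gait stability during treadmill
    walking. Computes the reference margin of stability (MoS) from optical
    marker trajectories using the extrapolated-centre-of-mass construction
    with a belt-speed correction, estimates per-step minimum MoS from
    six-axis inertial measurement unit (IMU) step signals using principal
    motion analysis (a partial-least-squares-derived time-series
    regression), and evaluates single- and dual-sensor body placements by
    repeated stratified cross-validation. Includes a synthetic treadmill
    gait generator with analytically known per-step MoS ground truth for
    validation and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    jsonlite,
    optparse
Config/testthat/edition: 3
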