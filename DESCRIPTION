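Package: escapekin
Title: Escape Kinematics and Ratiometric Calcium Imaging for Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for acoustically evoked escape responses in
    larval zebrafish and for calcium imaging of spinal neurons in moving
    animals. Extracts per-escape kinematic parameters (latency, C-bend
    amplitude, tail-beat frequency, oscillation count, distance, speed) from
    high-speed 11-point body tracks; tracks regions of interest across
    two-channel fluorescence movies by normalized cross-correlation and
    computes motion-corrected ratiometric (dR/R) and single-channel (dF/F)
    signals with stimulus-locked response amplitudes; fits nested linear
    mixed models for cohort comparisons across genotypes and repeated
    trials. Includes synthetic-data generators with known ground truth for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    tiff,
    jsonlite,
    lme4,
    lmerTest,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
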