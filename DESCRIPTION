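Package: tectovis
Title: Quantification Pipeline for Superior-Colliculus-Dependent Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for widefield calcium imaging, electrophysiology,
    fiber photometry and axonal anatomy experiments probing the tecto-thalamic
    (superior colliculus to pulvinar) drive of lateral higher visual areas in
    mouse cortex. Provides delta-F/F computation with isosbestic hemodynamic
    correction, patch-based retinotopic area delineation, silencing effect-size
    estimation (intra- and inter-hemispheric), the visuo-motor divergence (VMD)
    statistic for closed-loop treadmill experiments with Benjamini-Hochberg
    controlled time-course comparisons, spike detection with RS/FS waveform
    classification, PSTH and Z-scored firing-rate quantification, and laminar
    depth profiling of afferent fluorescence. A synthetic-data generator with
    known ground truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
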