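Package: territr
Title: Dyadic Territorial Behavior Analysis for Laboratory Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies territorial behavior and dominance in pairs of laboratory
    mice tested in a two-compartment arena. Computes region-of-interest dwell
    metrics (hiding, exploration, proximity, locomotion) from multi-animal pose
    tracks, event statistics from manually scored ethograms, flight-aligned
    speed and distance kinematics, a PCA-based dominance score with per-pair
    rank assignment, a cohort re-pairing permutation test, and dual-color
    urine-mark quantification from arena-floor photographs. Ships a seeded
    synthetic-cohort generator emulating the trajectory, event and image
    structure of the assay so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    pracma,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
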