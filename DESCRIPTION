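Package: fluorotrack
Title: Radiation-Free Digital Fluoroscopy Simulation for Guide-Wire
    Insertion Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating intraoperative fluoroscopy during
    dynamic hip screw (DHS) guide-wire insertion without ionising
    radiation. Camera frames containing two colored wire markers are
    segmented and tracked to sub-pixel centroids, mapped onto pre-loaded
    anterior-posterior and cross-table lateral hip radiographs through a
    three-point affine calibration, and overlaid as a simulated
    radiograph. Five objective performance metrics are recorded per
    session: tip-apex distance with radiographic magnification
    correction, predicted cut-out rate from a logistic risk curve,
    procedural time, radiograph count, and guide-wire retries. A
    construct-validity toolkit assigns surgeon cohorts by case count and
    compares them with Kruskal-Wallis and exact Mann-Whitney rank tests
    under a fixed multiplicity correction. Deterministic synthetic-data
    generators (frames, annotated radiographs, scripted trajectories,
    participant cohorts) make the full pipeline testable without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
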