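Package: tbiplan
Title: Multi-Isocenter VMAT Total Body Irradiation Planning Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for simulation-to-treatment planning of
    volumetric-modulated arc therapy total body irradiation (VMAT-TBI).
    Generates synthetic whole-body phantoms with paired head-first and
    feet-first CT scans, rigidly registers and stitches them into a
    whole-body volume, builds the planning target volume and divides it
    into VMAT and AP/PA sub-targets with optimization feathering zones,
    isocenters and junction points, constructs feathered AP/PA and
    step-wedge junction beams, computes composite dose on a 5 mm grid with
    a transparent primary-beam engine, recreates the classic extended-SSD
    AP/PA comparator with lung and kidney blocks, converts whole-body
    plans into head-first and feet-first delivery plans, and quantifies
    junction-dose robustness under per-isocenter setup errors with a
    longitudinal-locked image-guidance correction policy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
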