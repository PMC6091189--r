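Package: musclehca
Title: High-Content Analysis of Immunofluorescent Skeletal Muscle Sections
Version: 0.1.0
Authors@R: person("MuscleHCA", "Developers", role = c("aut", "cre"),
    email = "musclehca@example.org")
Description: Automated high-content analysis of immunofluorescently stained
    skeletal-muscle cross-sections. Segments every myofiber from the laminin
    (basal lamina) channel, derives regions of interest proportional to each
    fiber's minimum Feret diameter, and quantifies centronucleation,
    peripheral myonuclei, Pax7-positive satellite cells, CD31-positive
    vessels and up to three intrafiber stainings (fiber typing), with
    section-level quality control, color-coded in situ cartographies and
    batch reporting. Includes a seeded synthetic-section generator with
    complete per-fiber ground truth so the whole pipeline is testable
    without microscopy data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
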