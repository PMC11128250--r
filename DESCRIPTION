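Package: dcpt
Title: Treatment Planning and Dosimetric QA for Dynamically Collimated
    Pencil-Beam-Scanning Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale treatment planning chain for pencil-beam-scanning
    proton therapy with a sliding-bar dynamic collimation system. Generates
    analytic collimated beamlet kernel libraries with symmetry expansion,
    rasterizes planar test targets and peripheral rind regions, selects
    spots by a dose-ratio conformity criterion, assigns per-spot trimmer
    configurations by a collimation-level threshold, optimizes nonnegative
    spot weights to a uniform prescription dose, evaluates dose-area
    metrics, rind dose reductions and their depth and trimmer-to-surface
    distance trends, performs 2D gamma analysis and rigid registration QA,
    and emits layered delivery (PLD) files extended with per-spot trimmer
    positions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
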