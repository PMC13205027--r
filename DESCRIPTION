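Package: orgresponse
Title: Individual-Organoid Treatment-Response Analysis with Optical Redox Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying ex vivo treatment response of
    patient-derived cancer organoids (PDCOs) at the individual-organoid
    level. Tracks each organoid between a pre-treatment (Day 0) and a
    post-treatment (Day 4) imaging session, measures the relative change
    in longest diameter from brightfield images and the change in optical
    redox ratio (ORR = NAD(P)H / (NAD(P)H + FAD)) from widefield
    autofluorescence images restricted to the organoid leading edge,
    summarises treatment arms with a median-based Glass's delta effect
    size, classifies arms as sensitive / intermediate / resistant with
    treatment-class specific thresholds, and cross-tabulates predictions
    against RECIST v1.1 clinical response categories. Includes a synthetic
    gridded-dish imaging phantom generator (multi-channel fields with
    known per-organoid ground truth, a CellTiter-Glo-style well
    luminescence proxy, and simulated clinical sum-of-longest-diameter
    outcomes) so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
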