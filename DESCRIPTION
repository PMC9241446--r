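Package: bscbmark
Title: Quantitative MRI and Immunofluorescence Biomarkers of
    Blood-Spinal-Cord-Barrier Disruption
Version: 0.1.0
Authors@R:
    person("bscbmark", "developers", email = "bscbmark@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative imaging-biomarker analysis of
    blood-spinal-cord-barrier (BSCB) disruption and white-matter integrity
    in targeted experimental autoimmune encephalomyelitis (EAE).
    Implements diffusion-tensor fitting with FA/AD/RD scalar maps and
    white-matter-fraction threshold calibration, dynamic contrast-enhanced
    MRI gadolinium-influx (Kp-sc) scoring, Canny/fill-hole fluorescence
    vessel-pathology quantification, and the longitudinal
    correlation/regression/prediction framework linking imaging readouts
    to clinical score.  Ships seeded phantom and cohort generators with
    known ground truth so the whole pipeline is testable end to end, plus
    minimal NIfTI-1 and TIFF codecs and a command-line pipeline driver.
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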