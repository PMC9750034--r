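Package: fpgrade
Title: Quantitative Facial-Paralysis Assessment from Facial Animation Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative assessment of unilateral facial paralysis
    from Kinect-style facial animation unit (FAU) recordings. Computes static
    and dynamic animation symmetry indices (ASI) for the eyes, eyebrows and
    mouth; grades five voluntary facial movements (smiling, eye closure,
    raising eyebrows, blowing cheeks, whistling) per facial side on a 0-10
    scale from movement-minus-rest FAU changes; ranks the FAU-difference
    features with ReliefF; classifies the performed movement with a
    probabilistic support vector machine and reports a three-valued
    Yes/No/May-be ability decision under a confidence-margin rule; and
    assembles everything into a per-patient report. A synthetic session
    generator simulates normal subjects and unilateral-palsy patients with a
    controllable severity parameter, so the whole pipeline is testable
    without depth-camera hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
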