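Package: spineval
Title: Concurrent Validation of Instrumented Spine Motion Measurement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate joint-encoder based spinal motion measurement
    against an optical motion-capture reference. Converts encoder angles to
    anatomical cervical and lumbar orientations through Denavit-Hartenberg
    forward kinematics, estimates the constant alignment between the two
    measurement systems, synchronises and cleans the paired orientation
    streams, and computes the agreement statistics used in concurrent
    validity studies: root-mean-square error with interpretation bands,
    Bland-Altman bias and limits of agreement, parallel-forms reliability
    with standard error of measurement and minimal detectable change, and a
    one-sided non-inferiority test of motion speed. A synthetic dual-system
    study generator with a known ground-truth ledger makes every pipeline
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
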