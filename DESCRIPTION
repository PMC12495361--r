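Package: breathtrace
Title: Table-Motion-Corrected Respiratory Surrogate Signals for CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving a table-motion-corrected anterior-posterior
    breathing signal from dual optical-marker pose streams (a patient marker
    and a CT-couch reference marker), computing deep-inspiration breath-hold
    (DIBH) reproducibility and stability metrics as well as 4DCT amplitude,
    cycle-duration and baseline-shift metrics, driving a static or dynamic
    (cos^6 guidance) visual-feedback breathing window, and validating the
    whole pipeline against a built-in simulator of breathing patterns,
    load-dependent couch sag, camera pitch geometry, X-ray gating and
    optical tracking noise.
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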