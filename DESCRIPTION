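Package: swallowseg
Title: Automated Segmentation of Swallowing Sounds in Cervical
    Auscultation Audio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transfer-learning pipeline for detecting and time-stamping
    swallow events in cervical auscultation recordings. Audio is framed
    into 0.96 s windows with 50% overlap, converted to 96 x 64 log-Mel
    patches, mapped to fixed-length embeddings through a pluggable
    backend, concatenated with the frame zero-crossing rate, and scored
    by a fully-connected head that predicts swallow occupancy for six
    0.16 s subframes per frame. Overlapping subframe confidences are
    overlap-added into a recording-level timeline, thresholded, and
    decoded into time-stamped events. Includes event-overlap and
    subframe confusion-matrix evaluation, and a synthetic
    cervical-auscultation simulator so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
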