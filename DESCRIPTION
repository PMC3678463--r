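Package: qusbone
Title: Quantitative Ultrasound Gray-Level Depth-Profile Analysis of
    Femoral Subchondral Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies osteoarthritis-related sclerosis of femoral
    subchondral bone from B-mode knee ultrasound images. From a
    manually annotated cartilage-bone interface it extracts a
    rectangular region of interest, computes the normalized
    depth-ordered mean gray-level intensity profile (cut to start at
    the reflection maximum, resampled to a common pixel pitch and
    truncated to 25 samples), summarises it into five uniform depth
    levels, an overall mean and an intensity slope, and averages the
    three femoral sites (medial condyle, sulcus, lateral condyle) into
    a per-subject femoral summary. Includes ordinal grading utilities
    (Noyes conversion, composite femoral arthroscopic scores FAS1 and
    FAS2), Spearman rank correlation with Fisher r-to-Z confidence
    intervals, two-group t comparisons, correlation-table reporting,
    and a severity-linked synthetic B-mode phantom cohort generator so
    the whole pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
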