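Package: chromborders
Title: Graded Chromatin Borders and Domain States from Trimodal Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects graded signal borders and classifies inactive, primed and
    silenced chromatin domains from joint single-cell ATAC, H3K27ac and
    H3K27me3 fragment data. Includes fragment-file and contact-matrix input
    and output, per-cell quality control, pseudobulk track construction,
    within-cell mark grouping with a permutation test, contact-matrix
    balancing and insulation analytics, transcription-factor network strength
    statistics, differential accessibility with false-discovery-rate control,
    and a synthetic-data generator that emulates a HOX-like gene cluster with
    planted borders for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
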