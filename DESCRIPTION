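Package: pocbc
Title: Simulation and Clinical-Validation Toolkit for Image-Based Point-of-Care Blood Counting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating a point-of-care complete blood
    count (CBC) pipeline based on hemocytometer imaging and colorimetric
    hemoglobin strips. Provides a synthetic-data generator with known ground
    truth (virtual patient panels, rendered counting-chamber fields, strip
    images, and a simulated comparator analyzer), a deterministic tiled cell
    detector with overlap deduplication, count-to-concentration quantitation
    with derived hematimetric indices, morphological flagging (microcytosis,
    macrocytosis, anisocytosis, platelet clumps, immature cells), and the
    statistics battery used in clinical method validation: Bland-Altman
    agreement, Passing-Bablok regression, paired t tests, precision summaries
    against EFLM analytical performance goals, and confusion-matrix
    concordance with Cohen's kappa and balanced accuracy.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
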