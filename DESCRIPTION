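Package: fundusvit
Title: Vision-Transformer Screening for Glaucoma from Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated glaucoma screening from colour fundus
    photographs. Implements a from-scratch Vision Transformer bounding-box
    regressor for locating the optic disc and optic cup, the geometric
    cup-to-disc-ratio (CDR) diagnosis rule with a 0.6 decision threshold,
    a synthetic fundus image generator with exact box and label annotations,
    and detection/diagnosis evaluation metrics (IoU, accuracy, sensitivity,
    specificity, ROC/AUC, precision-recall/AP). The whole pipeline runs at
    desk scale on a single CPU with no external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    jpeg,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    digest,
    withr
Config/testthat/edition: 3
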