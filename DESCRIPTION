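Package: rbcscope
Title: Detect-Then-Classify Analysis of Red Blood Cell Morphology in
    Full-Scope Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for red blood cell (RBC) phenotyping in full-scope
    microscopy fields: a decoupled two-step pipeline (cell detection,
    patch standardization, fold-ensemble classification with
    confidence-weighted voting, back-annotation), class-imbalance
    mitigation operators (inverse / square-root-inverse /
    effective-number class weights, focal loss, image-level
    oversampling, targeted copy-paste augmentation, rare-class
    cropping), COCO JSON and YOLO text annotation IO, a complete
    detection and classification evaluation protocol (IoU matching,
    precision/recall/F1, Recall at IoU thresholds, COCO-style AP/mAP,
    macro and support-weighted averages), and a deterministic synthetic
    scene generator with five RBC phenotype archetypes and oracle
    detector/classifier stand-ins for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    nnet,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
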