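Package: nucleiprompt
Title: Prompt-Based Nuclei Segmentation and Classification with Category
    Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments and classifies cell nuclei in H&E histopathology tiles
    by prompting a frozen promptable mask decoder with learnable category
    descriptors, one token stack per nuclei type plus background and boundary
    channels. A lightweight inverted-residual domain-alignment adapter shifts
    low-level patch features while every backbone weight stays frozen.
    Training uses a federated multi-class hinge objective that only penalises
    classes present in the image and silences confidently classified pixels,
    together with repeat factor sampling for long-tailed class mixtures.
    Includes sliding-window inference with centroid-based stitching,
    boundary-channel instance decoding, interactive point-prompt refinement,
    object-level F1 and COCO-style mAP evaluation, and a synthetic H&E scene
    generator used as the test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
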