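Package: fakefoodr
Title: Automated Dietary Assessment for Fake-Food Buffet Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated dietary assessment built around fake-food
    buffet (FFB) studies: paired RGB image / pixel-level label-mask handling
    with reproducible train/validation/test splits and the four-step joint
    data augmentation (rotations, horizontal flip, colour noise on the image
    only, border zoom); semantic-segmentation evaluation via pooled confusion
    matrices and the four standard measures (pixel accuracy, mean accuracy,
    mean intersection over union, frequency-weighted intersection over
    union); and the StandFood food-name standardization chain (rule-based
    part-of-speech profiling, noun-index candidate retrieval with weighted
    lemma-set scoring, Levenshtein fallback, food-category classification and
    post-processing) linking recognized foods to FoodEx2-style codes and a
    food composition database. Includes a synthetic buffet-scene generator
    with exact ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    jsonlite,
    png,
    readr,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
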