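Package: mushgrade
Title: Morphometric Grading of Mushrooms from Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Appearance-quality grading of single mushrooms (Stropharia
    rugoso-annulata) from cap/stalk segmentation label masks. Recovers cap
    diameter and height and stalk length and diameter by minimum-area
    rotated-rectangle morphometry with upright re-alignment, computes the
    cap diameter-to-height ratio (RDHP) and stalk length-to-diameter ratio
    (RLDS), and assigns one of three appearance grades with an
    RLDS-prevails conflict rule and a broken-specimen bypass. Includes a
    deterministic synthetic mushroom renderer for ground-truthed testing,
    pixel-level segmentation evaluation metrics (precision/recall/F1,
    MIoU, MPA), per-grade-averaged grading accuracy, and a kinematic model
    of air-blown sorting that converts a grade decision into a lateral
    belt displacement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    utils,
    tibble,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
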