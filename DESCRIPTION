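Package: vesselseg
Title: Unsupervised Retinal Blood-Vessel Segmentation by Morphological
    Hessian Enhancement and Region-Based Otsu Thresholding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments the blood-vessel network in color fundus photographs
    without any training data. The pipeline enhances the green channel with
    contrast-limited adaptive histogram equalization (CLAHE), removes slow
    background variation with a modified morphological top-hat transform,
    scores tubular structure at a thin and a wide scale from the difference
    of the Hessian eigenvalues, classifies pixels by fusing a global Otsu
    threshold on the wide-vessel image with an offset region-based threshold
    map, and removes small spurious components. Includes pixel-wise
    evaluation metrics (accuracy, sensitivity, specificity, and their
    summary AUC), a synthetic fundus-image generator with exact ground
    truth, a batch harness for DRIVE/STARE-style folders, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
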