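Package: boutondetect
Title: Tracing-Free Detection of Axonal Boutons in Two-Photon Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects axonal boutons (presynaptic varicosities) in 3D
    two-photon microscopy stacks without tracing the axon backbone. The
    pipeline enhances blob-like structure on the mean-intensity projection
    with a negative Laplacian-of-Gaussian kernel, proposes candidate
    locations as determinant-of-Hessian interest points, cleans them with a
    two-window non-maximum suppression, describes each candidate with a
    12-filter Gabor bank, classifies candidates with a polynomial-kernel
    support vector machine, and localizes accepted boutons in depth by a
    patch-sum argmax over slices. Includes a box-based evaluation protocol
    (precision/recall/F1 and threshold-sweep curves) and a synthetic-stack
    generator with known ground truth for training and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    e1071,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
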