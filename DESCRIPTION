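Package: pssmloc
Title: Segmented Physicochemical and Evolutionary PSSM Features with a
    Rotation Forest Classifier for Protein Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts segmentation-based physicochemical descriptors
    (overlapped segmented density and autocorrelation) from evolutionary
    consensus sequences, together with semi-composition and auto-covariance
    descriptors taken directly from PSI-BLAST position-specific scoring
    matrices, assembling the 401-feature combined vector used for
    multi-class protein subcellular localization.  Ships a Rotation Forest
    ensemble classifier (per-tree random feature-subset PCA rotations over
    unpruned CART base learners with majority voting), a group-aware
    10-fold cross-validation harness with per-location accuracies, readers
    and writers for FASTA, ASCII PSSM, attribute-scale and dataset-manifest
    formats, and a synthetic fixture generator so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
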