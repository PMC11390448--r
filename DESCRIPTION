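Package: milct
Title: Weakly Supervised Multi-Instance Detection of Pancreatic Tumors in CT Volumes
Version: 0.1.0
Authors@R:
    person("Mira", "Kessler", email = "mira.kessler@example.org",
           role = c("aut", "cre"))
Description: A two-stage, weakly supervised pipeline for detecting pancreatic
    tumors in volumetric CT: organ-mask-guided cropping of the pancreas region
    into bags of 2D axial instances, K-means pseudo-labeling of instances
    inside positive bags, a softmax instance classifier, and a small neural
    aggregator that maps per-slice probabilities to a patient-level cancer
    probability. Includes a seeded synthetic phantom generator (ellipsoidal
    organ, spherical lesion, anisotropic spacing) so the full pipeline is
    testable without clinical data, series screening and spline/nearest
    resampling utilities, minimal NIfTI-1 input/output, and evaluation tools
    (sensitivity, specificity, accuracy, ROC AUC with DeLong confidence
    intervals, dice overlap).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
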