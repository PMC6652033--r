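Package: reflexquant
Title: Quantification and NINDS Classification of the Patellar Reflex from
    Inertial Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the patellar (knee-jerk) deep-tendon reflex
    from three-channel inertial recordings (impact pulse, knee angle, angular
    velocity sampled at 5 kHz). Provides a seeded synthetic-recording generator
    built on a damped-oscillation model with a slow return-to-baseline
    component, calibrated per NINDS grade (0+ to 3+) against published group
    feature statistics; impact-synchronised trimming and zero-phase Chebyshev
    type-I low-pass filtering; extraction of six biomechanical features
    (peak-to-peak excursion, first-to-third peak decay ratio, max-to-min and
    first-to-third peak intervals, 97 percent energy settling time, peak angular
    velocity); Kruskal-Wallis group-separation tests; and leave-one-out
    cross-validated classification into NINDS grades with Gaussian naive Bayes,
    k-nearest neighbours, linear SVM and bagged-tree classifiers, with optional
    PCA feature reduction. Recordings are read and written in a
    LabVIEW-measurement-style (LVM) tab-delimited text dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    randomForest,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
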