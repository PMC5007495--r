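Package: rhdtype
Title: Single-Molecule Fluorescence Image Analysis and Classification of
    Rhesus D Phenotypes
Version: 0.1.0
Authors@R:
    person("rhdtype", "developers", email = "rhdtype@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying blood samples into the four Rhesus D
    phenotypes (D+, weak D, DEL, D-) from single-molecule fluorescence
    microscopy of antibody-labelled erythrocytes. Provides a statistical
    image simulator (bright-field and fluorescence frames with ground
    truth), bright-field cell segmentation with a ring-kernel matched
    filter and greedy active contours, single-molecule peak detection by
    conservative smoothing, top-hat filtering, thresholding and region
    growing, per-cell and per-image feature extraction, binned
    peak-intensity distribution-overlap statistics, repeated
    cross-validated ensembles (random forest, RBF-SVM, kNN, genetic
    programming with offspring selection) with majority voting at image
    and sample level, and a rule-based fusion of the two into a final
    per-sample phenotype assignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
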