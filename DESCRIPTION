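Package: agefaces
Title: Age-Aware Synthetic Facial-Syndrome Cohorts, Classifier Ensembles,
    Conditional GAN Augmentation and Saliency Permutation Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying how age interacts with
    image-based diagnosis of genetic syndromes. Generates synthetic labelled
    image cohorts whose disease phenotypes drift across five age brackets,
    trains a four-label classifier with a confidence-filtered cross-validation
    ensemble (one-hot and soft-label cross-entropy), trains a conditional GAN
    whose label conditioning factorises into separate disease and age
    embedding matrices, produces four kinds of synthetic augmentation images
    (including embedding-interpolated age progression and soft-label disease
    blends), computes occlusion saliency maps and composites, and quantifies
    whether classifier-salient facial features differ between age groups with
    a permutation test on embedding distances. Includes survey-style
    human-versus-model accuracy tables, paired t-tests and per-cell
    permutation p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    png,
    Rcpp,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
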