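Package: fedalz
Title: Federated Learning with Secure Aggregation for Alzheimer's Disease
    Detection on Synthetic Structural MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates privacy-preserving federated learning for Alzheimer's
    disease (AD) versus cognitively normal (CN) classification from structural
    MRI-like volumes. Provides a synthetic cohort generator emulating an
    ADNI-style case/control study (per-subject 3D intensity volumes with a
    diagnosis-dependent atrophy signal plus demographics), ten heterogeneous
    client-partitioning scenarios (size-skewed, sex-, age- and
    diagnosis-imbalanced), a 3D convolutional neural network classifier
    trained with Adam, federated averaging (FedAvg) with an in-process
    client/server round simulator, SPDZ-style secure aggregation by additive
    secret sharing over a prime field with fixed-point encoding, a
    shadow-model membership-inference privacy evaluation, and the study
    protocol (repeated splits, balanced matched test sets, balanced accuracy,
    relative performance decrease).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    glmnet,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
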