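Package: ccnn
Title: Connectome-Convolutional Neural Networks for Functional Connectome Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Classification of functional brain connectomes with a
    connectome-convolutional neural network (CCNN) that convolves whole
    ROI connectivity fingerprints (1 x N row filters followed by N x 1
    column filters) over multi-channel connectivity matrices, together
    with matched dense-network baselines. Includes connectivity metrics
    computed from ROI time series (Pearson correlation, Dynamic Time
    Warping distance and warping path length under a Sakoe-Chiba band),
    a simulated connectome benchmark generator with ground-truth
    modified ROIs, subject-grouped cross-validation with accuracy and
    AUC, a cumulative-binomial chance baseline, an exact discordant-pair
    test for comparing classifiers, and first-layer weight summaries for
    recovering the ROIs that drive classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
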