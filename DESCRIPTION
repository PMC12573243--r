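Package: metanet
Title: Meta-Representations of Neural Networks via Weight-Space Autoencoding
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Embeds populations of small patch autoencoders ("first-order
    networks") into a low-dimensional meta-representation space by
    autoencoding their weight matrices. A two-stage meta-autoencoder (a
    unitwise convolutional stage over individual 16x16 filters followed by
    canonical filter sorting and an interunit linear stage) maps each
    256x16 encoder weight matrix to a 16-dimensional embedding; a
    k-nearest-neighbour meta-classifier on those embeddings recovers the
    sensory modality and category of the data each network was trained on.
    Includes a synthetic patch generator with controllable vision-like and
    audio-like second-order statistics, patch extraction from images and
    audio, model-zoo training and serialization, evaluation reports with
    confusion matrices, an exact t-SNE implementation for visualisation,
    and a config-driven experiment runner with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
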