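Package: lraecg
Title: Low-Rank Attention Autoencoder for ECG Beat Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies electrocardiogram (ECG) beats and rhythm strips with a
    low-rank attention (LRA) autoencoder: a non-trainable attention matrix is
    derived from the singular value decomposition of the Gram matrix of the
    input features, double-normalized, and applied as a constant weighting to
    every encoder layer of a tanh autoencoder; the latent representation feeds
    a one-dimensional ResNet-18 classifier. Includes Z-score preprocessing and
    beat segmentation for annotated records, readers for WFDB and CSV fixture
    formats, a seeded synthetic ECG generator covering four beat morphologies
    and four rhythm classes, training with hand-written backpropagation and
    Adam, one-vs-rest evaluation metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rlang,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
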