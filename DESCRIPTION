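Package: mnporigin
Title: Origin Classification and Misannotation Cleaning for Marine Natural Products
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Structure-based classification of marine natural products into
    their biological origin kingdoms (Animalia, Bacteria, Fungi) and detection
    of origin misannotations caused by host-microbe symbiosis. Provides a
    directed message-passing molecular encoder with a feed-forward
    classification head, a microbial pretraining / frozen fine-tuning scheme,
    a two-step label-cleaning workflow (out-of-fold cross-prediction screening
    followed by embedding-neighborhood filtering), physicochemical and
    scaffold-level profiling, downstream SVM and gradient-boosted heads with
    balanced-accuracy evaluation, Monte Carlo tree search extraction of
    predictive substructures, and a template-grammar generator of three
    structurally separable synthetic compound classes with plantable label
    noise for end-to-end testing without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    e1071,
    xgboost,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
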