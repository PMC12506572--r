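Package: ribolift
Title: Prediction and Generative Optimization of 5' UTR Ribosome Loading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the mean ribosome loading (MRL) of 5' UTR
    sequences and for rewriting a query UTR into a nearby sequence with higher
    predicted MRL. Implements a residual convolutional + GRU regression model
    trained on MPRA-style (sequence, MRL) libraries, successive-halving
    hyperparameter search, greedy weight-averaging model soups,
    permutation-sampling Shapley attribution of sequence features, and a
    generative autoencoder trained with a composite reconstruction +
    ribosome-loading loss against a frozen predictor. Includes a seeded
    synthetic MPRA oracle for end-to-end validation, sequence-pair analytics
    (substitution matrices, content shifts, uAUG counts, Hausdorff distances),
    and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
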