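Package: qmetric
Title: Quantum Metric Learning Classifiers with a Fidelity Kernel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Trains a hybrid classical-quantum embedding for binary
    classification of tabular feature data. A 2xn linear projection maps n
    input features to two angles that drive a two-qubit variational circuit
    (alternating Rx data encoding, ZZ entanglers and Ry rotations); all
    2n + 12 parameters are optimized with RMSProp to minimize a
    Hilbert-Schmidt cost between the class-ensemble density matrices.
    Trained embeddings are used by a fidelity (state-overlap) kernel
    classifier. Includes per-feature standardization and PCA front-ends
    fitted on training data, a two-class synthetic data generator with
    controllable dimensionality and separation, Gram-matrix and scatter
    exports, and a sweep driver for studying generalization as the
    parameter count varies relative to the sample count.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
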