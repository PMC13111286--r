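Package: qspiral
Title: Hybrid Quantum-Classical Classification of Handwriting Exam Drawings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dual-track hybrid quantum-classical network for classifying
    Parkinson's disease from hand-drawn spiral and meander exam images plus
    structured clinical features. Provides a synthetic exam generator with a
    controllable tremor model, the grayscale-suppression preprocessing
    pipeline, an attention-augmented ghost-convolution image encoder feeding
    an amplitude-embedded variational quantum circuit, an RY-encoded
    strongly-entangling circuit for tabular features, a fusion classifier
    trained with focal loss, stratified cross-validation with bootstrap
    confidence intervals, and Grad-CAM plus perturbation-based feature
    sensitivity for explainability. Quantum circuits are simulated exactly on
    the statevector with adjoint-mode gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    stats,
    utils,
    grDevices,
    tools,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
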