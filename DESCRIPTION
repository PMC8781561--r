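Package: chaoscrypt
Title: Chaos-Based Encryption and Security Analysis for Grayscale Medical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encrypts 8-bit grayscale medical images with a chaos-based
    permutation-substitution cipher. A heterogeneous pseudo-random generator,
    structured as a four-layer neural network whose neuron transfer functions
    are chaotic maps (logistic, piecewise-linear, logistic-tent, cubic), expands
    a 64-bit key into the keystreams that drive a pixel-position permutation
    (P-box) and a per-pixel substitution plus DNA-complement bit permutation
    (SP-box). Includes the matching security-evaluation suite (MSE, PSNR,
    Shannon entropy, adjacent-pixel correlation, GLCM energy and contrast),
    salt-and-pepper noise-attack analysis, ensemble hard/soft voting rules, and
    seeded synthetic chest-radiograph-like test images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
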