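Package: freqlens
Title: Spatial-Frequency Bias Analysis for Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures which spatial-frequency bands an image classifier
    relies on and how that bias relates to robustness. Provides hybrid-image
    probing with reversal-frequency estimation, Fourier analysis of minimal
    adversarial perturbations (half-power frequency of the radial power
    profile), a minimal L-infinity perturbation search aggregating projected
    gradient descent candidates over engines and seeds, a procedural
    common-corruption suite grouped by frequency content, fixed Gaussian-blur
    and PCA-projection preprocessing defenses with exact gradient chaining,
    representational-similarity eigenanalysis with linear receptive-field
    mapping, and synthetic-data generators (band-structured image classes,
    oracle classifiers, tiny trainable convolutional networks, V1-like
    response matrices) so every analysis runs end-to-end on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
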