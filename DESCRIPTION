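Package: latentmorph
Title: Latent-Space Simulation of Disease Progression in Brain MR Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Style-based generative modelling of 2D brain MR slices with
    latent-space projection (GAN inversion), support-vector-machine semantic
    directions for simulated multiple-sclerosis progression, and brain
    parenchymal fraction morphometry. The whole pipeline is exercised
    end-to-end on synthetic multi-echo brain phantoms with known tissue
    masks, which double as ground-truth oracles for the morphometry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    e1071,
    png,
    RNifti,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
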