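Package: dsitract
Title: Diffusion Spectrum Imaging Reconstruction, Tractography and Phantom
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for diffusion spectrum imaging (DSI) of the rodent
    brain after focal ischemia: construction of the 203-point Cartesian
    q-space encoding scheme, multi-tensor fiber phantoms with stroke
    scenarios (white-matter remodeling, severed callosal bridge),
    propagator and orientation distribution function reconstruction,
    generalized fractional anisotropy mapping, deterministic streamline
    tractography with interhemispheric-connection assessment, region
    statistics with one-way ANOVA and Holm-Sidak comparisons, and
    block-design BOLD activation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    RNifti,
    mclust,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
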