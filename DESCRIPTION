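Package: qctrends
Title: Entropy-Based Complexity Trends for Beat-to-Beat Hemodynamic Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a bounded, entropy-based complexity statistic for
    multivariate beat-to-beat cardiovascular recordings. Pairwise dependencies
    between hemodynamic variables (so-called generalized correlations) are
    detected from rank-binned scatter-plot images using Shannon entropy and a
    permutation surrogate test; complexity is the spectral norm of the Hadamard
    product of the resulting adjacency and entropy matrices, reported together
    with its lower and upper bounds, per-variable complexity profiles and a
    dependency map. Includes impedance-cardiography parameter derivation
    (stroke volume, cardiac output, Heather index, arterial compliance,
    vascular resistance), a sliding-window trend pipeline with gap handling and
    event detection for head-up tilt testing, and a synthetic tilt-test
    generator with vasovagal collapse scenarios for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
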