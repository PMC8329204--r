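Package: lmmd
Title: Logarithmic Mueller Matrix Decomposition and Collagen Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-pixel logarithmic (differential) decomposition of
    transmission Mueller matrix images into polarization and depolarization
    parameter maps (linear retardance, optical-axis azimuth, linear
    depolarization), thickness-mitigating normalized and fused maps, and
    whole-image statistical scoring of collagen fiber alignment (moments,
    two-Gaussian histogram fits, circular azimuth statistics).  Includes a
    forward simulator of birefringent, depolarizing tissue-section phantoms
    modeled on a transverse uterine-cervix cross-section, for validation
    and method development.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    e1071
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
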