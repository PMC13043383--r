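Package: coelomyx
Title: Simulation and Analysis of the Sea Urchin Coelomocyte DNA-Damage
    Response
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Desk-scale reimplementation of a coelomocyte UVB-challenge
    analysis workflow: synthetic UMI and bulk count generation with planted
    structure, MAD-based single-cell quality control, marker-signature
    coelomocyte cell typing, negative-binomial bulk differential expression
    with gene clustering, depth-aware gene-gene co-expression estimation
    from UMI counts with a permutation differential-co-expression test,
    gene-set over-representation, and quantification of functional assays
    (logistic LD50 dose-response, comet tail-DNA percent, fluorescence
    puncta density, western blot densitometry).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    methods,
    minpack.lm,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
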