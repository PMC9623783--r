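Package: igpred
Title: Indirect Genomic Prediction with Single-Step GBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-step genomic BLUP (ssGBLUP) for animal breeding at desk
    scale: pedigree relationship matrices and Henderson's sparse inverse,
    VanRaden genomic relationships with blending, the APY (algorithm of
    proven and young) sparse inverse, a matrix-free preconditioned
    conjugate-gradient solver for multi-trait mixed model equations with
    repeated records, SNP-effect backsolving from GEBV, indirect genomic
    prediction (IGP) of young genotyped animals, and the regression-based
    bias and accuracy validation of IGP against benchmark GEBV.  Includes a
    gene-dropping population simulator with directional selection for
    end-to-end verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
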