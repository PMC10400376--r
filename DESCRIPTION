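Package: seq2expr
Title: Convolutional Sequence-to-Expression Modeling and Design of Short
    Regulatory DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models expression driven by short regulatory DNA sequences
    measured in gigantic parallel reporter assays (GPRA). Recasts the
    sequence-to-expression regression task as soft classification over 18
    sorting bins with a Kullback-Leibler loss and soft-argmax decoding,
    implements an EfficientNetV2-style fully convolutional network with
    squeeze-and-excitation blocks and residual channel-wise concatenation,
    reverse-complement and singleton-aware input encoding, one-cycle
    cosine learning-rate training with AdamW or Lion, test-time
    augmentation and seed ensembling, variant-effect estimation by
    prediction differencing, and cold-diffusion design of promoter
    sequences with a target expression level. A synthetic GPRA simulator
    with a planted motif grammar provides a desk-scale oracle for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
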