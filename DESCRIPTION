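Package: promdiff
Title: Multinomial Diffusion Models for De Novo Promoter Sequence Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative design of fixed-length bacterial promoter sequences
    with a multinomial (categorical) diffusion model, paired with a
    convolutional sequence-to-expression regressor for scoring candidates.
    Provides the full forward/reverse categorical diffusion machinery
    (noise schedules, closed-form marginals and posteriors, variational
    step losses), a block-local transformer denoiser and a 1D-CNN predictor
    implemented on base matrix algebra, simulators for planted motif-pair
    corpora and promoter-like benchmarks with noisy expression labels, and
    an evaluation suite covering GC-content Jensen-Shannon divergence,
    k-mer frequency correlation, intra-sample edit-distance diversity,
    poly-A/T screening, PSSM motif scanning, inter-motif spacer analysis,
    and a cross-entropy decoupling score for motif-pair grammars.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
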