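Package: assemblage
Title: Hippocampal-Prefrontal Cell-Assembly and Population-Decoding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for simultaneously recorded hippocampal (dCA1)
    and medial prefrontal (mPFC) spike trains from delayed non-match to sample
    (DNMTS) sessions. Provides kernel-density firing-rate estimation with
    unbiased cross-validated bandwidths, time-resolved single-unit cue
    discrimination (t-score profiles), regularized linear-discriminant
    population decoding with leave-one-out cross-validation and shuffle nulls,
    cross-temporal decoding grids, factor-analysis based detection of within-
    and inter-area cell assemblies with trial-shuffle bootstrap model
    selection, an independent-component cross-check, rank-ordered synthetic
    assembly benchmarking, rhythmic (4-5 Hz) spike-pair physiology
    (autocorrelograms, multitaper coherence, rate-matched cross-correlograms,
    LFP phase locking), and an inhomogeneous-Poisson DNMTS session simulator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
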