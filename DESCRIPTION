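Package: histgate
Title: Outcome-Gated Trial-History Biases in Two-Alternative Choice Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of history-dependent perceptual
    decisions in block-structured two-alternative forced choice (2AFC)
    tasks. Provides a Markov-chain stimulus-sequence generator with
    stretched-beta frame evidence and amplitude-modulated envelopes, a
    generative latent-variable agent in which a reward-driven gating
    signal modulates the influence of accumulated transition evidence on
    choice, exact maximum-a-posteriori fitting of that model, a
    trial-history probit GLM with lapse rates and repetition/alternation
    transition kernels, psychometric-curve estimation of fixed side and
    repeating biases with bootstrap uncertainty, and the lag-k
    outcome-conditioned transfer-coefficient analysis that discriminates
    complete-reset from gated dynamics of the transition bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
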