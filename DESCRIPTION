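Package: dyntrf
Title: Dynamic Temporal Response Functions via State-Space Models with
    Gaussian Mixture Process Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear state-space models whose process noise is drawn from a
    Gaussian mixture, one mixture component per window of consecutive state
    steps, with expectation-maximization parameter estimation. The E-step is
    approximated either in closed form by a two-filter Gaussian-sum smoother
    with mixture reduction, or by sequential Monte Carlo particle smoothing
    over per-window state blocks. The models are applied to dynamic estimation
    of auditory temporal response functions (TRFs) from continuous speech
    envelopes and a single-channel neural response, with regularized recursive
    least squares and Markov-switching autoregressive benchmarks, M100-based
    auditory attention decoding, and a synthetic cocktail-party scenario
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
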