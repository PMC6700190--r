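Package: ntmdetect
Title: Normalized Template Matching for Extracellular Spike Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two-round spike detection for tetrode extracellular recordings.
    A first round of standard fixed-voltage-threshold detection (with shadow
    period, clip extraction and negative-peak alignment) yields per-unit mean
    waveform templates; a second round detects spikes by sliding cosine
    similarity between the multichannel voltage signal and each template
    (normalized template matching, NTM), with per-unit similarity thresholds
    chosen by an ROC rule that maximizes the mean of true-positive and
    correct-rejection rates. Includes the unnormalized sliding dot-product
    variant (TM), preprocessing (common average referencing, zero-phase
    band-pass filtering, kurtosis-based tetrode pad selection), single-unit
    quality metrics (refractory violations, truncated-Gaussian missing-spike
    estimates, Mahalanobis distances), a ground-truth surrogate voltage
    simulator (stimulus-locked Bernoulli single units, inhomogeneous-Poisson
    multi-unit background, waveform insertion with sub-millisecond jitter),
    and a benchmarking suite that scores detection against known spike times
    across first-round threshold sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
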