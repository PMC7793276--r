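Package: spectralTE
Title: Spectrally-Resolved Multivariate Transfer Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies which wavelet-scale frequency bands of a source process
    send, and which bands of a target process receive, information, without
    filtering the analysed signals. Frequency specificity is obtained by
    destroying the temporal order of a single scale's maximal-overlap discrete
    wavelet transform (MODWT) coefficients in surrogate data only, and testing
    for a drop in nearest-neighbour (Kraskov) multivariate transfer entropy
    relative to the original estimate. Includes a nested swap-out/swap-out
    (SOSO) permutation test for direct band-to-band transfer, seeded
    generators for nine validation systems with known ground truth, and a
    small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
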