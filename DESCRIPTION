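Package: ppgclean
Title: Motion-Artifact Removal from Two-Channel Photoplethysmograms by
    Constrained ICA and Adaptive Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes motion artifacts from two-channel (red/infrared)
    photoplethysmographic (PPG) recordings while preserving the per-channel
    amplitude information needed for pulse oximetry. A temporally constrained
    independent component analysis (cICA, "ICA with reference") extracts the
    single PPG-correlated component from the two channels using a periodic
    rectangular reference built from the autocorrelation-estimated pulse
    period; an LMS adaptive filter then restores each channel's amplitude,
    splitting every channel exactly into a recovered PPG part and a motion
    artifact estimate. Includes FFT-LMS and moving-average-filter baselines,
    a synthetic PPG/artifact generator with SNR-controlled mixing, and a
    Monte-Carlo RRMSE evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
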