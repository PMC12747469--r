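Package: clusterless
Title: Clusterless State-Space Decoding with Streaming Replay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Real-time style clusterless decoding of linearized position from
    unsorted spike waveform features. Implements kernel joint-mark-intensity
    encoding models, a recursive Bayesian filter over position bins, online
    sharp-wave-ripple detection from LFP, and remote-representation event
    detection, together with a deterministic file-replay runtime, a binary
    results-record format, and a ground-truthed synthetic session generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
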