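Package: radarvitals
Title: Contactless Vital-Signs Monitoring with Simulated SFCW MIMO Radar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and signal-processing toolkit for contactless
    monitoring of respiration and sleep pose with a stepped-frequency
    continuous-wave (SFCW) MIMO radar and an L-shaped antenna array. The
    package generates synthetic time-varying point-scatterer scenes of a
    breathing person in bed, evaluates the bistatic SFCW received-signal
    model, reconstructs complex 3D radar images (range, azimuth, elevation)
    with a windowed matched filter and its 3D-FFT fast path, reduces image
    sequences to a compact per-window representation, and derives amplitude,
    phase-evolution and distance-evolution indicator maps. On top of those it
    provides threshold classifiers for presence and limb-movement detection,
    a forked convolutional network for sleep-pose classification and torso
    joint regression with an angular loss, and respiratory-motion extraction
    with STFT harmonic-summation breathing-rate estimation and a windowed
    chest-abdomen phase-shift indicator for paradoxical-breathing detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
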