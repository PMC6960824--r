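Package: fallradar
Title: Fall Detection with Multiple Continuous-Wave Doppler Bioradars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for contactless human fall
    detection with a pair of continuous-wave (CW) Doppler bioradars. Generates
    physically motivated synthetic two-channel (I/Q) baseband radar records for
    falls and daily activities under a five-subject, two-radar study design;
    demodulates quadrature pairs by principal component analysis; suppresses
    sub-5 Hz physiological components with a zero-phase Butterworth filter;
    converts motion signals to analytic Morlet wavelet scalograms rendered as
    227x227x3 images; classifies fall vs. not-fall with a compact convolutional
    neural network trained from scratch; and fuses per-radar softmax
    probabilities into a single orientation-robust decision, reporting
    accuracy, sensitivity, specificity, precision and F1-score under
    subject-wise train/test splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
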