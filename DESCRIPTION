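Package: ssvepDecode
Title: Decoding Feature-Based Attention from Frequency-Tagged EEG
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and benchmarking single-trial decoders of
    feature-based visual attention from frequency-tagged EEG. The package
    simulates a cued motion-discrimination task in which two intermingled
    random-dot fields flicker at 6.0 and 7.5 Hz, generates multi-participant
    synthetic EEG with steady-state visual evoked potentials (SSVEPs),
    alpha activity, 1/f background noise, motion-locked transients and
    artifacts, and writes the result as a BIDS-EEG dataset in the
    BrainVision format with an HDF5 behavioural container. Downstream it
    extracts sliding-window FFT amplitude features under amplitude and
    motion-contamination exclusion rules, classifies the attended colour
    with six algorithms (z-score difference, LDA, logistic regression by
    SGD, RBF-SVM, multi-layer perceptron, 1-NN) under trial-wise
    cross-validation or transfer from distractor-absent training, and
    models accuracy as a saturating inverse-exponential function of the
    sliding-window size.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    class,
    e1071,
    minpack.lm,
    jsonlite,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, Electroencephalography, Classification, Preprocessing
RoxygenNote: 7.3.3
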