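Package: ergsynth
Title: Synthetic Electroretinogram Waveforms for Class-Imbalance Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, synthesis and evaluation tools for full-field
    light-adapted electroretinogram (ERG) waveforms. Provides a
    physiologically shaped simulator for single-flash (LA3) and 30 Hz
    flicker responses, a conditional generative adversarial network that
    learns class-conditioned waveform distributions and samples synthetic
    minority-class records, Fourier low-pass post-processing, a-wave and
    b-wave time-domain feature extraction by peak detection, and a
    random-forest evaluation harness that compares classification of an
    imbalanced trait (sex) on original, randomly oversampled and
    GAN-augmented training sets using balanced accuracy, precision, recall
    and F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
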