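Package: ecgfusion
Title: Hybrid ECG-Image Diagnosis via Feature Matrices and Audio Spectrograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-subsystem toolkit for classifying single-lead ECG plot images,
    built around a fully synthetic, ground-truth-annotated ECG generator. ECG plot
    images are digitized (grayscale, Gaussian blur, adaptive threshold, largest
    8-connected contour, column-wise amplitude extraction), converted to normalized
    audio waveforms and log-Mel spectrograms, and classified by two independently
    trained models: a residual-block network feeding a bidirectional-RNN
    encoder-decoder over per-beat feature matrices, and a compact convolutional
    spectrogram classifier with SpecAugment-style masking. Predictions are combined
    by weighted aggregation. Grad-CAM heatmaps with quantitative region-attention
    metrics, confusion-matrix statistics, ROC/AUC, stratified splits and
    stratified k-fold cross-validation complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
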