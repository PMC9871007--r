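Package: auscult
Title: Pediatric Lung-Sound Synthesis, Preprocessing and Ensemble-SVM Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying pediatric auscultation clips into normal,
    crackle and wheeze classes. Provides a physics-informed synthetic
    auscultation-audio generator (vesicular breath noise, damped-sinusoid
    crackles, tonal wheezes, heart-sound contamination), BayesShrink wavelet
    denoising, fixed 6-second windowing by the duplicate-and-crop rule,
    mel-spectrogram and MFCC feature extraction, majority-voting ensembles of
    RBF-kernel support vector machines for four binary classification tasks,
    stratified K-fold and nested cross-validation with accuracy, precision,
    recall and F1 reporting, chi-square comparison against human raters,
    ICBHI-2017-style annotation parsing, and UMAP embedding of feature
    vectors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster
SystemRequirements: Python (>= 3.8) with numpy and umap-learn on PATH as
    'python' (only for umapEmbed()).
Config/testthat/edition: 3
RoxygenNote: 7.3.3
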