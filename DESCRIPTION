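Package: gaitWNN
Title: Joint Angle Estimation from Vertical Ground Reaction Forces with
    Wavelet Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates sagittal ankle, knee, and hip joint-angle profiles
    from vertical ground reaction force (vGRF) inputs alone, using a
    two-layer wavelet neural network with Mexican-hat wavelon activations
    trained by gradient descent with momentum.  Implements the
    gait-intervals (GI) feature selection scheme that reduces a normalized
    gait cycle to 22 salient vGRF features located at nine primary and 13
    intermediate gait events, heuristic initialization of wavelon
    translation and dilation parameters, prediction-risk based selection
    of the hidden-layer size, spline reconstruction of full angle
    profiles, and RMSE/NRMSE/Pearson scoring with in-sample/out-sample
    reporting.  Includes a synthetic gait cohort generator producing
    paired kinetic/kinematic cycles with subject- and trial-level
    variability, and a sigmoid multilayer-perceptron baseline trained
    under a matched budget.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
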