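Package: speckleglucose
Title: Noninvasive Speckle-Based Blood Glucose Sensing Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for noncontact blood glucose
    classification from laser speckle videos recorded under an AC magnetic
    field. Provides closed-form magneto-optic (Faraday rotation) and
    Beer-Lambert attenuation models, a synthetic speckle-video generator with
    glucose-dependent modulation at the magnetic drive frequency, FFT-based
    cross-correlation displacement tracking with subpixel refinement,
    frequency-domain lock-in extraction of the drive-frequency component,
    SVM classification with Gaussian-process Bayesian hyperparameter search,
    a compact CNN-LSTM sequence classifier trained on frame-difference
    stacks, and confusion-matrix evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    tiff,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
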