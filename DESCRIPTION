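Package: ktmnet
Title: Kernelized and Tensorized Multitask Networks for Modelling Alzheimer's
    Disease Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint 4-class diagnostic staging (AD, MCI converter, MCI
    non-converter, cognitively normal) and longitudinal regression of the
    Mini-Mental State Examination at four timepoints (baseline, 6, 12 and 24
    months) from fused multimodal tabular features. Implements a multitask
    neural network that encodes each modality block (MRI, PET, cognitive,
    CSF, risk factors) with linear layers, fuses them, maps the fused vector
    through a layer of Gaussian radial-basis units with learnable centers and
    bandwidths, reshapes the result into a spatial map processed by dilated
    stride-1 convolution branches and a convolutional feature extractor, and
    feeds a shared representation to a softmax classification head and a
    non-negative regression head trained under a weighted sum of mean squared
    error and categorical cross-entropy. Ships cohort preprocessing
    (complete-case filtering, analyte range filtering, leakage-feature
    removal, train-statistics z-scoring), a calibrated synthetic-cohort
    generator, a nested cross-validation protocol with grid search and early
    stopping, evaluation metrics (per-timepoint RMSE and correlation,
    one-vs-rest AUC, confusion matrices), design-exploration ablations, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
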