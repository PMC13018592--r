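Package: CascadeCT
Title: Uncertainty-Aware Cascaded CNN Classification of Ischemic Stroke CT Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lightweight residual convolutional network for binary
    ischemic-stroke-versus-normal classification of 2-D CT slices, with an
    integrated Monte-Carlo-dropout uncertainty module (normalized predictive
    entropy, dropout-rate calibration, entropy rejection), a quantitative
    saliency module (Grad-CAM, Grad-CAM++, Score-CAM; mean saliency intensity
    scoring and saliency-driven label correction), and a cascaded decision
    pipeline that accepts, flips, or refers each prediction for expert review.
    Includes a reproducible synthetic head-phantom generator with ground-truth
    lesion masks, and an evaluation suite covering Wilson confidence intervals,
    MoRF perturbation faithfulness, calibration metrics (ECE, MCE, Brier) with
    temperature scaling, and risk-coverage analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
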