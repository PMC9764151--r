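Package: ecgkalemia
Title: Personalized Deep Transfer Learning for Hyperkalemia Detection from
    Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects hyperkalemia (serum potassium above 5.5 mEq/L) from
    single-lead ambulatory electrocardiograms. Provides a seeded synthetic
    ECG cohort generator with potassium-dependent beat morphology and strong
    intersubject heterogeneity; beat-level preprocessing (zero-phase FIR
    band-pass filtering, automated quality control, Pan-Tompkins style
    R-peak detection, 120-sample beat segmentation, potassium labelling);
    a from-scratch 1D preactivation bottleneck residual network (ResNet-50
    layout, with a ResNet-18 variant) trained by Adam with a plateau
    learning-rate schedule; round-based patient-adaptive transfer learning
    with layer freezing; record-level classification by majority voting with
    accuracy/AUC/sensitivity/specificity and exact Mann-Whitney U tests; and
    Grad-CAM saliency plus t-SNE embedding of learned beat features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
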