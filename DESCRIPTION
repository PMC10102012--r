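Package: retinaCL
Title: Style-Transfer-Augmented Contrastive Pretraining for Referable
    Diabetic Retinopathy Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised contrastive pretraining of a fundus-image
    encoder with adaptive-instance-normalization (AdaIN) style-transfer
    augmentation, followed by supervised fine-tuning for referable versus
    non-referable diabetic retinopathy. Includes a seeded synthetic
    fundus and style-texture generator so the whole pipeline runs at desk
    scale, label-fraction experiments, and ROC evaluation with DeLong
    confidence intervals, Youden operating points and paired DeLong
    tests. The contrastive stage uses the normalized temperature-scaled
    cross-entropy (NT-Xent) loss with a LARS optimizer; networks are
    small convolutional encoders trained on the CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
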