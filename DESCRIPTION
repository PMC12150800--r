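Package: csvdseg
Title: Multi-Output U-Net Segmentation and Quantification of Cerebral Small Vessel Disease Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of a multi-output U-shaped segmentation
    network (MO-UNet) for the four classical neuroimaging markers of cerebral
    small vessel disease (white matter hyperintensities, cerebral microbleeds,
    lacunes and enlarged perivascular spaces) on multisequence brain MRI
    (T1-weighted, FLAIR, SWI). Provides a synthetic multisequence phantom
    generator with exact ground truth, slice preprocessing and positive-sample
    augmentation, an autoencoder-pretrained MBConv encoder with
    sequence-routed scSE decoders trained with a combined cross-entropy and
    Dice loss, segmentation evaluation metrics (precision, specificity, Dice,
    95th-percentile Hausdorff distance, lesion-wise sensitivity with bootstrap
    confidence intervals), and volumetric burden quantification (visual-score
    binning, total burden score, cohort Z-score burden, Pearson/Bland-Altman
    agreement and ANOVA with LSD post-hoc tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
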