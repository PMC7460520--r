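Package: myoinvade
Title: Myometrial Invasion Staging from Uterine MR-Like Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for pre-operative staging of stage-I
    endometrial cancer from sagittal uterine images. Generates synthetic
    uterine phantoms with analytically known myometrial-invasion fractions,
    standardizes and augments images, trains a compact encoder-decoder
    (U-Net style) segmentation network with a soft-Dice loss, converts
    uterus and lesion masks into an invasion-depth fraction by radial
    profiling with a robust trigonometric fit of the endomyometrial
    junction, classifies FIGO IA versus IB at the 50 percent cutoff, and
    runs the concordance statistics (accuracy, over- and under-staging
    rates, Pearson chi-square, correlation, one-way ANOVA, five-number
    summaries) used to compare machine and radiologist staging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
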