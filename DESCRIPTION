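Package: lungqct
Title: Quantitative CT of Emphysema, Air Trapping and Airway Dimensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative computed-tomography measures of pulmonary emphysema,
    air trapping and airway dimensions, together with the agreement statistics
    used to compare paired image-reconstruction algorithms. Implements
    histogram densitometry of masked lung volumes (density-mask indices,
    attenuation percentiles, expiratory/inspiratory ratios), threshold-based
    lung segmentation with explicit failure signaling, full-width-at-half-maximum
    ray-casting airway morphometry, Lin's concordance correlation with a
    descriptive agreement scale and an exact Wilcoxon signed-rank test, and a
    synthetic thoracic phantom generator that renders paired
    inspiratory/expiratory volumes under filtered back-projection and
    iterative-reconstruction noise levels so reconstruction sensitivity can be
    studied end to end without patient data.
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
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
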