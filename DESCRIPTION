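Package: tubulequant
Title: Automated Tubule Nuclei Quantification in H&E Breast Cancer Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tubule formation in hematoxylin-and-eosin stained
    breast cancer high power fields. Nuclei candidates are detected with a
    blue ratio transform, Otsu thresholding and morphological opening;
    64x64 RGB patches around each candidate are classified as tubule or
    non-tubule nuclei by a small convolutional neural network; the tubule
    formation indicator (the ratio of tubule nuclei to all detected nuclei)
    is aggregated per slide and related to Oncotype DX risk categories and
    Bloom-Richardson grade through Welch t-tests and ROC analysis. A
    synthetic field generator produces H&E-like images with ground-truth
    nuclei and tubule polygon annotations so the whole pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
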