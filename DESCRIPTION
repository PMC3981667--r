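Package: forestpair
Title: Automated Pair-Wise Forest Disturbance Mapping from Bi-Temporal
    Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps forest disturbance from a pair of co-registered
    multispectral scenes (Landsat TM/ETM+-like top-of-atmosphere
    reflectance plus a thermal band) with no manual training input.
    The pipeline screens clouds, cloud shadows and water, delineates
    forest from local red-band histogram dark peaks, extracts labelled
    training pixels by local-window thresholding of the shortwave
    infrared difference image, purges mislabelled samples with a
    four-classifier consensus filter under cross-validation, classifies
    the multi-temporal tasseled-cap feature stack with a radial-basis
    support vector machine, and converts per-pixel labels to a
    polygon-based six-category change map through morphological
    cleaning, region-merging segmentation, plurality labelling and a
    minimum mapping unit. Includes a synthetic scene generator with
    per-pixel truth and stratified accuracy-assessment machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    rpart,
    nnet,
    class,
    stats,
    graphics,
    utils,
    tiff,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
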