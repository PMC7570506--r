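Package: hsipix
Title: Pixel-Wise Classification of Near-Infrared Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infrastructure and classifiers for pixel-wise classification of
    near-infrared hyperspectral reflectance images of food products.
    Provides a hypercube container with ENVI and portable readers/writers,
    band-arithmetic background masking, chemometric spectral pre-treatments
    (standard normal variate, Savitzky-Golay first derivative, external
    parameter orthogonalization), PCA score-image projection, PLS2
    discriminant analysis with venetian-blinds cross-validation, multiclass
    support vector machines via error-correcting output codes, compact 2-D
    and 3-D convolutional neural networks trained on per-pixel patches,
    confusion-matrix evaluation, and a synthetic scene generator with exact
    ground truth for end-to-end testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    tiff,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
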