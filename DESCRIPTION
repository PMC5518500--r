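Package: medsrr
Title: Single-Image x4 Super-Resolution with Exact Bicubic Template Layers and
    SIFT-Based Transfer Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single-image x4 super-resolution of grayscale
    (medical) images. Derives, in exact integer arithmetic, the 16 bicubic
    convolution templates (4x4 integer stencils over a common denominator of
    2^18) that realise cubic convolution interpolation at the quarter-pixel
    midpoints, and applies them as the frozen first layer of a hybrid
    convolutional network whose two remaining layers (patch
    extraction/representation and nonlinear mapping plus a linear
    reconstruction) are trained by stochastic gradient descent on a
    mean-squared-error loss. Includes a SIFT-feature transfer-learning
    selector that enlarges a small domain-specific training corpus from a
    generic image pool, paired training-set construction by random cropping
    and x4 area down-scaling, PSNR and region-wise evaluation, seeded
    synthetic image fixtures, and a command-line pipeline front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
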