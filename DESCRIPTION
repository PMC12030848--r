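Package: dynspec
Title: Multispectral Pixel Classification with Dynamic Convolution,
    Selective-Kernel Attention and Recurrent Spectral Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-wise land-cover classification of multispectral
    reflectance imagery. Spectral features are extracted by two parallel
    branches - an omni-dimensional dynamic convolution whose effective
    kernel is an attention-weighted convex combination of candidate
    kernels, and an improved large-selective-kernel block that gates
    depthwise multi-scale branches through sigmoid spatial selection
    masks with an optional multi-head attention refinement - fused and
    fed band-by-band through a two-layer gated recurrent unit and a
    multi-layer perceptron head. Includes a seeded synthetic
    multispectral scene simulator, region-of-interest sample handling,
    cross-entropy training with per-epoch learning-rate decay,
    confusion-matrix accuracy metrics (overall accuracy, average
    accuracy, Cohen's kappa), and land-cover change-dynamics analysis
    (per-class areas, change rates, class-transition matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
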