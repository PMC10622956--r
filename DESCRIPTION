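Package: ecaselect
Title: Learnable EEG Channel Selection with Efficient Channel Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Embedded channel selection for motor-imagery brain-computer
    interfaces. A channel-attention (CA) layer placed in front of a deep
    convolutional network learns a weight for every EEG electrode while the
    network is trained to classify motor-imagery trials; the learned weights
    rank the electrodes, and a subset of any size is taken as a ranking
    prefix and the network retrained on it. Includes the full attention-
    augmented DeepNet architecture (temporal and spatial convolutions, four
    convolution-pooling blocks with efficient-channel-attention modules and
    a convolutional classifier head), the signal pipeline (band-pass
    filtering, exponential-moving-average standardization, sliding-window
    trial cropping), and a synthetic motor-imagery generator with planted
    informative channels so the whole selection loop can be exercised and
    validated without any EEG recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
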