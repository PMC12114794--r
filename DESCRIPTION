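Package: crossburn
Title: Cross-Resolution Burnt-Area Mapping with Encoder-Decoder Segmentation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cross-resolution burnt-area delineation from
    multispectral satellite imagery. Generates co-registered very
    high-resolution (3 m) and medium-resolution (30 m) synthetic reflectance
    scenes with ground-truth burn scars, derives burnt-area labels by forest
    masking and per-band min/max spectral thresholding, transfers
    fine-resolution labels to coarse grids by burnt-coverage fraction, trains
    UNET and UNET-GRU semantic-segmentation networks (implemented natively,
    including convolution, gated recurrent bottleneck, Adam, dropout,
    learning-rate plateau scheduling and best-epoch checkpointing) on
    medium-resolution tiles, and evaluates predictions with a full
    segmentation metric suite (precision, recall, F1, accuracy, burnt-class
    IoU, Dice) and whole-scene pixel accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    yaml,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
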