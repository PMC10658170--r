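Package: sparsevox
Title: Sparse Convolutional Networks for Binary Voxel Shape Completion
    and Super-Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A sparse convolutional neural network engine for spatially
    sparse binary voxel occupancy grids, with applications to cranial
    implant generation (skull shape completion) and binary shape
    super-resolution.  Sparse tensors store only the occupied voxels;
    coordinate management uses FNV-1a 64-bit hashing with exact-key
    chaining.  The engine provides sparse convolutions, generative
    transposed convolutions that create new points, and score-based
    pruning layers, assembled into an encoder-decoder trained with
    binary cross-entropy.  Analytic parameter, activation-size and FLOP
    cost models, a synthetic skull-shell generator with simulated
    craniotomy defects, NRRD/NIfTI voxel-grid input and output, and
    segmentation evaluation metrics (DSC, reconstruction error, border
    DSC, HD95) are included, together with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
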