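Package: spotlight3d
Title: Foreground-Aware Training and Evaluation for 3D Virtual Staining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a foreground-aware training objective for 3D virtual
    staining of fluorescence volumes from transmitted-light input: an
    Otsu-derived foreground mask restricts the pixel-wise mean squared error
    to informative voxels, and a Dice loss on a soft-thresholded prediction
    enforces shape fidelity. Ships a small 3D encoder-decoder backbone with
    hand-written reverse-mode gradients, a seeded generator of paired
    synthetic nucleus volumes with anisotropic axial-elongation artifacts,
    and the full evaluation stack: whole-image and foreground-restricted
    PSNR and 3D structural similarity, Fourier shell correlation resolution
    estimates, watershed instance segmentation scored by average precision
    at multiple IoU levels, intensity-threshold sweeps, and per-nucleus
    morphological profiling compared by cosine distance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tiff,
    jsonlite,
    igraph
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
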