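Package: minidiffusion
Title: Denoising Diffusion Models for Small Grayscale Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Train denoising diffusion probabilistic models (DDPM) on small
    (28x28) grayscale medical image stacks such as the ChestMNIST subset of
    MedMNIST v2, and generate new images by ancestral reverse diffusion. The
    noise predictor is a compact U-Net with residual blocks, group
    normalization, multi-head self-attention and sinusoidal timestep
    embeddings, trained under L1, L2 or Huber noise-prediction losses with an
    Adam optimizer; forward and backward passes are implemented directly on
    BLAS-backed matrix operations. Generation quality is quantified with a
    Frechet distance evaluator over pluggable feature extractors at
    configurable dimensions (64, 2048), using a deterministic orthogonal
    projection extractor by default. A synthetic chest-phantom generator
    provides a download-free stand-in distribution with controllable body
    shape, posture, lung volume, gray value and field-of-view variability.
    Includes MedMNIST-layout NPZ readers and writers, PNG image-grid export,
    YAML run configuration and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    jsonlite
Config/testthat/edition: 3
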