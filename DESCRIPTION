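Package: dmrisynth
Title: Manifold-Aware Synthesis of Diffusion MRI from Structural Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesis of high-resolution diffusion tensor (DT) and diffusion
    orientation distribution function (ODF) volumes from scalar structural MRI,
    with every synthesized voxel guaranteed to be mathematically valid. Diffusion
    tensors are handled through the log-Euclidean framework on the manifold of
    symmetric positive-definite matrices, and ODFs through the square-root
    spherical-harmonic re-parameterization on the unit Hilbert sphere, so that
    networks operate in a flat tangent space and the exponential maps enforce
    validity by construction. Includes an unpaired cycle-consistent adversarial
    training scheme with paired priors and anisotropy-weighted losses, a
    configurable fiber-bundle phantom generator, evaluation metrics (principal
    direction cosine similarity, FA/GFA mean squared error, mean geodesic
    distance, invalid-voxel counts), and deterministic peak-following streamline
    tractography with bundle-overlap statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    pracma
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'dmrisynth-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'odf.R'
    'spd.R'
    'tractometry.R'
    'evaluation.R'
    'phantom.R'
    'objectives.R'
    'nnet.R'
    'networks.R'
    'training.R'
    'io.R'
    'cli.R'
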