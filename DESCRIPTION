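Package: rotormap
Title: Phase Mapping and Rotor Localization for Cardiac Excitation Waves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Tools for computing phase maps and locating phase singularities
    (rotor cores) in movies of cardiac electrical excitation. Includes a
    two-variable reaction-diffusion simulator of spiral wave chaos for
    generating training and test data, classical phase mapping (Hilbert
    transform, delay embedding, linear upstroke interpolation), line-integral
    phase singularity detection, degradation operators emulating noisy,
    low-resolution and electrode-sparse recordings, a kernel-based phase
    restoration reference pipeline (Kuramoto outlier removal, inpainting,
    spatio-temporal smoothing), a compact convolutional encoder-decoder
    engine for image-to-image phase and singularity prediction, and an
    evaluation suite (angular accuracy, radius-matched precision/recall,
    average Hausdorff distances).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'rotormap-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'apsim.R'
    'phasecore.R'
    'singularity.R'
    'metrics.R'
    'degrade.R'
    'restore.R'
    'utils.R'
    'io.R'
    'nets-core.R'
    'nets-model.R'
    'pipeline.R'
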