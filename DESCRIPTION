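Package: famcirc
Title: Plastic Recurrent Cortical Circuit Model of Familiarity Training
    and Neural Manifold Compression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a firing-rate excitatory-inhibitory recurrent
    circuit of early visual cortex with a convolutional sparse-coding
    front end and plastic excitatory horizontal connections (BCM or
    general Hebbian rule with synaptic-resource normalization).
    Provides synthetic texture stimuli with salt-and-pepper occlusion
    variants, familiarity-effect statistics (suppression index,
    lifetime sparsity, population tuning curves), manifold geometry
    metrics (signal, level and residual distances and their relative
    compression), and a collective-mode linearization of the attractor
    dynamics with alignment, spectrum and sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    png,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'famcirc-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'manifold.R'
    'utils.R'
    'frontend.R'
    'stimuli.R'
    'plasticity.R'
    'circuit.R'
    'runner.R'
    'linear.R'
    'analyze.R'
    'familiarity.R'
    'io.R'
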