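Package: qlandmark
Title: Deep Q-Learning Landmark Localization in 3D Medical Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reinforcement-learning localization of anatomical landmarks in 3D
    scalar volumes (CT-like images). An agent walks the voxel grid observing
    2.5D states (three orthogonal patches plus a short observation history)
    and is trained with a dueling deep Q-network whose encoder shares
    convolution weights across time but not across image axes. Includes the
    Markov decision process environment with a squared-distance reward,
    experience-replay training, a coarse-to-fine multi-agent localization
    procedure, a FLOPs accountant for the network architecture, a synthetic
    phantom generator (bright spheroid with an attached tube whose junction is
    the target landmark, emulating a coronary ostium on the aortic root), and
    a command-line interface. Volume I/O supports NIfTI and MetaImage formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
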