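Package: aacdenoise
Title: Unpaired Low-Dose CT Denoising with an Anti-Aliased Cycle-Consistent
    GAN and k-NN Precision/Recall Evaluation
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for unpaired translation between low-dose and
    standard-dose CT slices: an anti-aliased generator (blur-pool
    down-sampling, sub-pixel up-sampling, hierarchical feature synthesis
    with concurrent spatial/channel squeeze-excitation gates), a
    three-scale patch discriminator bank, the joint
    adversarial/cycle/identity objective, a CPU training loop with a
    minimal reverse-mode autodiff core, a synthetic phantom generator with
    dose-dependent noise, CT slice I/O (NPZ, PNG, single-frame DICOM), and
    the improved k-nearest-neighbor manifold precision/recall evaluator
    for generative models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
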