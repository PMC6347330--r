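Package: deeprecon
Title: Deep Image Reconstruction from Decoded Neural Network Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs visual images from fMRI voxel activity by decoding
    hierarchical convolutional-network features with sparse Bayesian (ARD)
    linear regression, then optimizing pixels -- or the latent code of a
    generator network -- so that the multi-layer features of the candidate
    image match the decoded features. Includes the block-design fMRI
    preprocessing pipeline (nuisance regression, rest normalization,
    despiking, hemodynamic-shifted block averaging), a pairwise
    identification / winning-percentage evaluation protocol, and a synthetic
    data stack (stimulus generators, linear voxel encoding model, run
    simulator) so the full pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
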