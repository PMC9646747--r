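Package: allopath
Title: Allosteric Coupling Pathways and Gating Analysis for Ion Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying allosteric coupling between a ligand
    binding site and the pore of an ion channel from conformational
    ensembles, together with the standard electrophysiology analyses used
    to validate such couplings. Builds residue interaction networks from
    trajectory contact occupancy and dynamic cross-correlations, extracts
    optimal and suboptimal source-to-sink coupling paths (Floyd-Warshall
    plus k-shortest simple paths), and computes per-residue current-flow
    "information flow" on a mutual-information-weighted network Laplacian
    with Gaussian-mixture entropy estimation. Includes Boltzmann
    conductance-voltage fitting, Hill dose-response fitting with
    Monte-Carlo standard errors, NPo estimation from current traces, and
    channel-count estimation. A synthetic-data module generates Gaussian
    network model bead trajectories with analytically known covariance,
    plus synthetic gating curves and multi-channel current traces, so
    every estimator can be validated against closed-form ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    mclust,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    bio3d,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
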