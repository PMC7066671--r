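Package: pairpot
Title: Relative Potency Prediction for Congeneric Ligand Series with a
    Twin 3D Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts relative binding potency (delta-pIC50) between pairs
    of congeneric ligands posed in a shared protein pocket.  Protein-ligand
    complexes are voxelized onto an 18-channel occupancy grid (8
    pharmacophoric protein channels, 10 element ligand channels) and fed
    through a two-legged 3D convolutional network with tied weights; the
    difference of the two 192-dimensional latents through a bias-free linear
    head makes predictions antisymmetric by construction.  Includes
    continuous-learning evaluation protocols (random, temporal and
    chemical-similarity splits), maximum-a-posteriori absolute-affinity
    reconstruction from multiple references, an upper-confidence-bound
    driven lead-optimization campaign simulator, and a fully synthetic
    toy-series generator so the whole pipeline runs self-contained.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    ChemmineR,
    graphics,
    igraph,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
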