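Package: conjmap
Title: Conformational Landscape Analysis of Two-Domain Protein Conjugates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ensemble characterization of covalently linked two-domain
    protein conjugates such as ubiquitin dimers. Computes residue-wise
    minimum-distance (RMD) descriptors from coarse-grained or atomistic
    trajectories, projects them to two dimensions with landmark-based
    sketch-map nonlinear multidimensional scaling, builds Boltzmann-inverted
    free-energy surfaces with basin detection and representative-frame
    selection, compares landscapes by exact Earth Mover Distance, and
    analyses solvent-accessible surface areas: interface area and polarity,
    binding-patch accessibility and residue-wise buried surface. Includes a
    synthetic rigid-body ensemble generator with known basin structure for
    validation, and a configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    graphics,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
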