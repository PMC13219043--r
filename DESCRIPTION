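Package: navreg
Title: Two-Stage Rigid Registration of Sparse Probe Points to CT Bone Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient registration for image-guided orthopaedic navigation: aligns a
    sparse set of tracked-probe surface points to a dense CT-derived bone surface
    point cloud. Implements three-point (Kabsch/SVD) coarse alignment from paired
    landmarks followed by a sparse point-to-plane iterative closest point refinement
    in which an Lp (0<p<1) sparsity-inducing norm on point-to-plane residuals is
    minimised by the alternating direction method of multipliers, down-weighting
    outlier correspondences such as cartilage stand-off points. Includes PCA surface
    normal estimation with exact kd-tree neighbour search, readers and writers for
    STL/PLY/OBJ meshes and point/landmark tables, a synthetic bone-phantom generator
    with known ground-truth transforms, and a target-registration-error evaluation
    protocol with repeated paired trials, ablation configurations and sampling-count
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
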