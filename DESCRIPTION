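Package: foldflow
Title: Curvature-Tension Analysis of Epithelial Fold Fronts
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measurement and modelling pipeline for epithelial fold
    invagination viewed in transverse (medial-lateral x depth) sections.
    Tracks fold-front polylines over developmental time, estimates local
    curvature by circumcircle fits and local normal deepening speed,
    registers movies in space and time against anatomical landmarks,
    converts laser-ablation recoil displacement traces into a tension proxy,
    and tests the Laplace-force model in which normal deepening speed is
    proportional to the product of local curvature and in-plane tension via
    an origin-constrained collapse fit. Includes a forward simulator of the
    curvature-tension flow, synthetic generators for fronts, recoil traces,
    fiber images and z-stacks with known ground truth, and the image
    operators (apical surface detection, offset projection, fiber
    skeletonization and orientation, curvature-binned intensity) needed to
    quantify actomyosin organization around the fold.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
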