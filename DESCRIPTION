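Package: muscleArch
Title: Muscle Architecture from Diffusion Tensor Tractography and 2D Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction and comparison of pennate muscle architecture
    (fascicle length, pennation angle, muscle thickness) in vivo. Implements
    deterministic streamline tractography on diffusion-tensor volumes with
    fractional-anisotropy and curvature stopping rules, surface-mesh
    construction from segmentation label maps with shrink-free Taubin
    smoothing, median-endpoint fascicle reconstruction against the muscle
    surface, an ultrasound-style 2D measurement model, rigid marker-based
    registration of a tracked ultrasound scan plane into MR space, and exact
    Wilcoxon signed-rank comparison of paired ultrasound and DTI
    measurements. Ships a synthetic unipennate muscle phantom generator with
    analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
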