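Package: primage
Title: Brain Age Estimation for Non-Human Primate Structural MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained brain age gap estimation (BrainAGE) framework
    for non-human primate structural MRI, modelled on the baboon. Provides a
    seeded generator of 3D brain phantoms with programmed age-, sex- and
    group-dependent tissue composition; a voxel-based-morphometry style
    preprocessing chain (slice-gain inhomogeneity correction, adaptive
    non-local-means denoising, affine registration, EM tissue segmentation
    against a tissue probability map); iterative construction of a
    species-specific template and tissue probability map; PCA feature
    reduction and a sparse Bayesian linear-kernel relevance vector regression
    of chronological age with leave-one-out cross-validation; and the
    morphometric statistics layer (linear/quadratic volume trajectory fits,
    summary-statistic ANOVA, ANCOVA with partial eta squared, BrainAGE group
    contrasts).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
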