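Package: autoplan
Title: Automated IMRT Treatment Planning on Synthetic Pelvic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale toolkit for automated intensity-modulated
    radiotherapy (IMRT) planning. Generates reproducible synthetic pelvic
    phantoms (body, PTV, bladder, femoral heads), builds a pencil-beam
    dose-influence matrix for equiangular coplanar beams, produces a
    voxel-wise reference dose either from a deterministic geometric
    surrogate or a miniature trainable 3D U-Net, and optimizes beamlet
    fluences against that reference with a voxel mean-square-error
    objective optionally augmented by clinical homogeneity-index and
    conformity-index objectives. Includes the full dosimetric evaluation
    battery: DVH curves, D_X and V_D indices, homogeneity and conformity
    indices, global maximum dose, and paired cohort comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
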