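Package: HistoMRIfuse
Title: Histology to Multiparametric MRI Co-Registration for Soft-Tissue Tumor Specimens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatially exact co-registration of whole-mount histopathology
    with in vivo multiparametric MRI of soft-tissue sarcoma specimens. Provides
    landmark-driven closed-form rigid alignment of ex vivo to in vivo MRI, derivation
    of angle-plate settings for agarose-block trimming by Rodrigues back-rotation,
    4 mm grid slice planning and histology-to-MRI slice matching, thin-plate-spline
    nonrigid registration of digitized sections to MRI slices, a repeated
    random-split target-registration-error protocol with nonparametric group
    comparisons, voxel-wise k-means habitat clustering of co-registered quantitative
    parametric maps, and a synthetic phantom generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    RNifti,
    jsonlite,
    tiff,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
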