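Package: CartilageDice
Title: Silhouette and Registration Based Consistency Validation for 3D
    Cartilage Segmentation Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Validation pipeline for 3D knee-cartilage segmentation models
    against physical gold standards. Implements calibrated silhouette
    projection ("simulated photography") of tibial-plateau cartilage models
    with principal-axis pose rectification for 2D Dice comparison against
    specimen photographs, landmark-initialised iterative-closest-point rigid
    registration for 3D Dice and volume comparison against CT-derived
    reference models, and cohort-level aggregation with Pearson volume
    correlation. Ships a seeded synthetic tibial-plateau phantom generator
    (paired CT/MRI-frame label volumes with controlled thickness bias, defects,
    landmarks and a top-down photograph) so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), methods
Imports:
    Rcpp,
    RNifti,
    png,
    EBImage,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
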