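Package: rabatlas
Title: Multi-Atlas Segmentation Toolkit for the Neonatal Rabbit Brain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and using a multi-atlas of the neonatal
    rabbit brain from micro-MRI: stereotaxic reorientation from
    bicommissural landmarks, mid-sagittal symmetrization, diffeomorphic
    segmentation propagation with stationary velocity fields, label
    fusion by majority voting, multi-label STAPLE and LNCC-ranked
    selective fusion (STEPS), four segmentation-similarity metrics
    (Dice, covariance distance, Hausdorff, normalized symmetric contour
    distance), leave-one-out validation, probabilistic atlas
    construction, and a seeded synthetic phantom population for
    end-to-end testing without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
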