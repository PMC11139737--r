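Package: dynodose
Title: Internal Dosimetry from Dynamic Whole-Body PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Organ-level and voxel-level internal dosimetry for short-lived
    PET tracers imaged dynamically on long axial field-of-view scanners,
    with rubidium-82 chloride myocardial perfusion imaging as the motivating
    application. Extracts decay-corrected organ time-activity curves from
    4-D dynamic images and label maps, fits double-exponential kinetics,
    integrates analytically to normalized time-integrated activity, and
    computes MIRD-schema organ absorbed doses and ICRP-103 effective dose
    with pluggable S-value tables. A voxel branch computes time-integrated
    activity maps by trapezoidal integration with a mono-exponential tail
    and converts them to absorbed-dose maps. A synthetic dynamic-PET
    generator with known ground-truth kinetics supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
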