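Package: xcalqc
Title: Quality Control for PET/CT Cross-Calibration with Sealed Ge-68/Ga-68 Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring PET scanner and dose-calibrator calibration
    bias with long-lived sealed Ge-68/Ga-68 phantom kits. Implements
    decay-corrected traceable reference values, fully automated phantom
    localisation and whole-voxel cubic-bounding-box region-of-interest
    extraction from PET images, recovery-coefficient and SUV-bias metrics with
    coefficient-of-variation summaries, longitudinal and multisite reporting,
    a PET/CT alignment check, and a synthetic phantom-image simulator so the
    entire analysis chain can be exercised without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
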