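Package: sctdosim
Title: Bulk Electron-Density Synthetic CT Dosimetry for MR-Guided Adaptive Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate bulk relative-electron-density (rED) synthetic CT
    generation for MR-guided online adaptive radiotherapy of the head and neck.
    Provides a seeded digital head-phantom generator, HU-to-rED calibration and
    threshold segmentation of bone and air, construction of bulk-assigned
    synthetic CTs (homogeneous water, ICRU Report 46 constants, and
    patient-tailored mean rED), a simplified divergent-beam dose engine with an
    optional magnetic-field boundary perturbation, and the standard dosimetric
    comparison instruments: 3D global gamma analysis, point-dose differences,
    dose-volume-histogram metrics, and paired Wilcoxon signed-rank statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
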