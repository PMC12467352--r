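Package: rsfCBF
Title: Voxel-Wise Prediction of Cerebral Blood Flow from Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts regional cerebral blood flow (rCBF) from resting-state
    functional MRI at the voxel level, with partial volume averaging (PVA)
    correction based on gray-matter tissue occupancy. Voxel time series are
    reduced to an eight-bin spectral power schema, augmented with the six
    face-adjacent neighbours' band powers and the voxel's gray-matter
    occupancy, and mapped to CBF with a radial-basis-function support vector
    regression tuned by cross-validation. Includes regional (Desikan-Killiany
    style) averaging, predicted-versus-measured correlation analysis, Fisher
    r-to-z model comparison, Bonferroni correction, case-control Cohen's d
    effect sizes with cross-modality agreement statistics, and a synthetic
    cohort generator (cortical-ribbon phantom, band-limited BOLD-like series,
    forward PVA mixing model) so the full pipeline is testable without
    external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
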