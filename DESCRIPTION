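Package: ctecv
Title: Myocardial Extracellular Volume Quantification from Cardiac CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies myocardial extracellular volume (ECV) from paired
    pre-contrast and delayed-phase cardiac CT volumes: intensity-based rigid
    and deformable registration, subtraction imaging, left-ventricular
    segmentation with the AHA 16-segment parcellation, per-segment ECV with
    delayed-enhancement pattern classification, and a polar-map display.
    Companion tools cover dynamic CT perfusion (maximum-slope myocardial
    blood flow and the summed stress score), Agatston calcium scoring,
    CAD-RADS banding, chamber volumetry with body-surface-area indexing,
    and the cohort statistics used in reproducibility studies (normality
    routing, two-group tests, propensity matching, Bland-Altman, coefficient
    of variation, intraclass correlation, and t-test sample size). A seeded
    digital left-ventricle phantom with known ground truth supports
    end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    RNifti,
    jsonlite,
    stats,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
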