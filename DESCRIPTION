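Package: renalpet
Title: Kidney Function Estimation from Dynamic FDG-PET Time-Activity Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates glomerular filtration rate (GFR) and effective renal
    plasma flow (ERPF) from dynamic FDG-PET renal time-activity curves (TACs).
    Implements Bezier-type TAC smoothing, Patlak graphical analysis with a
    peak-anchored two-minute fit window, a peak-maximum over peak-integral
    ERPF estimator, activity-balance partial-volume correction of the aortic
    input function, reference-method calculators (CKD-EPI creatinine eGFR and
    single-sample MAG3 plasma clearance), method-agreement statistics
    (Pearson, paired t, Bland-Altman), and a tracer-kinetic simulator with
    known ground truth for validating every estimator without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    RNifti,
    optparse
Config/testthat/edition: 3
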