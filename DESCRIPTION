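Package: cranioflow
Title: Cerebral Hydro-Hemodynamics from Cardiac-Gated Phase-Contrast MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cerebral arterial, venous and cerebrospinal fluid (CSF)
    flow from cardiac-gated 2D phase-contrast MRI cine series: velocity
    aliasing detection and correction, waveform-correlation region growing as
    a reproducible stand-in for semi-automated lumen segmentation, flow-curve
    reconstruction, composite arterial/venous flows with the alpha venous
    correction, blood and CSF stroke volumes by cyclic trapezoidal
    integration, and pulsatility indices. Ships a synthetic cine generator
    with closed-form ground truth (pulsatile disk lumens, velocity wrap,
    additive phase noise) so the whole pipeline is testable without scanner
    data, plus a cohort simulator and the normality-gated statistical layer
    used to compare young and elderly groups.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
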