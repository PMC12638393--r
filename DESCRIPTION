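Package: csfpulse
Title: Phase-Contrast MRI Quantification of Cerebrospinal Fluid Pulsatility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies cerebrospinal fluid (CSF) stroke volumes from cine
    phase-contrast MRI: phase-to-velocity calibration with velocity-encoding
    (venc) aliasing correction and background offset removal, pulsatility-map
    region growing for semi-automatic lumen segmentation, flow-curve
    integration into stroke and net volumes at five craniospinal sites, and
    simple morphometric indices (Evans index, narrowest aqueductal area).
    Includes an analytic pulsatile-flow phantom generator and a synthetic
    cohort simulator so the full pipeline - including the two-group
    prognostic comparison between patients with and without postoperative
    headache relief in Chiari malformation type 1 - can be exercised and
    tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    pracma,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
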