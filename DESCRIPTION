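Package: pacemapr
Title: Pace-Mapping Localization of Premature Ventricular Contraction Origins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for localizing the origin of premature ventricular
    contractions (PVC) from multi-site endocardial pace mapping with 12-lead
    ECG. Implements four patient-specific localizers: a QRS-integral
    regression model (QIM), two scalar morphology-distance models based on
    the E12 root-mean-square difference (DEM) and the mean 12-lead Pearson
    correlation (DCM) combined with least-squares multilateration, and a
    transfer-matrix model that maps waveform-difference vectors to
    position-difference vectors (DDM). Also provides an emulation of the
    iterative clinical modeling/prediction protocol, outcome metrics
    (hit rates, estimated-error and reduced-distance curves, target-range
    summaries), a dipole-based synthetic paced-ECG generator for validation,
    and a plain-text dataset container with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
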