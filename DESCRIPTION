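Package: rsbci
Title: Respiration-Synchronized fNIRS Brain-Computer Interface Simulation,
    Decoding and Rehabilitation Task Personalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for respiration-synchronized functional near-infrared
    spectroscopy (fNIRS) brain-computer interfaces. Simulates respiration,
    dual-wavelength optical intensity with task-locked hemodynamic responses
    and physiological confounds, and normative versus impaired joint-angle
    kinematics. Implements causal inhalation detection and inhalation-locked
    cue scheduling, modified Beer-Lambert conversion of optical density to
    oxy-/deoxyhemoglobin, trial epoching, the dispersion index of pre-cue
    HbO baselines, spatial-temporal motor-imagery decoding with shrinkage
    linear discriminant analysis and cross-validation, and an ability-data
    personalization engine that scores upper-limb tasks against age-matched
    normative movement with dynamic time warping, screens them against 95
    percent normative intervals, weights joints by range of motion, and
    ranks rehabilitation tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    Rcpp,
    rlang,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
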