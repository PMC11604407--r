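Package: cardiogate
Title: Intrinsic Retrospective Cardiorespiratory Gating for Micro-CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for ECG-less (intrinsic)
    retrospective cardiac gating of micro-CT projection data. Provides a
    4D digital mouse-thorax phantom with a contracting, contrast-enhanced
    left-ventricular cavity and respiratory diaphragm motion; a
    parallel-beam projection simulator; extraction of cardiac and
    respiratory surrogate signals from projections by template
    co-registration (mutual information) and ROI intensity sums;
    inspiration-phase rejection; per-beat cardiac phase assignment and
    binning into 12 phases; filtered back-projection and ordered-subset
    iterative reconstruction of per-phase sinograms; and cardiac-function
    readouts (ejection fraction, fractional shortening, segmental
    myocardial strain, severity stratification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    Rcpp,
    signal,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
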