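Package: osseoquant
Title: Multi-Modal Quantification of Degrading Bone-Implant Systems
Version: 0.1.0
Authors@R:
    person("OsseoQuant", "Developers", email = "osseoquant@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify osseointegration and degradation of
    biodegradable (Mg-Gd) and permanent (Ti, PEEK) bone implants from four
    imaging modalities: micro-CT morphometry on labeled volumes (degradation
    rate, bone-to-implant contact, bone volume fraction in a peri-implant
    region of interest), X-ray fluorescence elemental-map segmentation and
    Ca/P-versus-distance profiling, SAXS/WAXS bone-ultrastructure analysis
    (azimuthal integration, stack-of-cards platelet thickness, Bragg
    d-spacing, Scherrer crystallite size), and LA-ICP-TOF-MS elemental
    quantification (gelatin-standard calibration, limit of detection,
    percentile-rule region classification). A synthetic phantom generator
    with exact ground truth makes every stage testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
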