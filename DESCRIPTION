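Package: surglabels
Title: Replay-Based Automatic Annotation of Tracked Laparoscopic Surgery
    Sessions
Version: 0.1.0
Authors@R:
    person("surglabels", "developers", email = "surglabels@example.org",
           role = c("aut", "cre"))
Description: Turns recorded, calibrated, time-synchronized tracked-surgery
    sessions into dense frame-level annotations: semantic label maps rendered
    from registered anatomy meshes, amodal and occlusion-aware instrument
    masks, depth and chromadepth images, instrument-tissue distance series,
    and rule-based surgical action triplets with hysteresis and temporal
    smoothing.  Includes the supporting calibration chain (pivot, hand-eye,
    point-based rigid registration), a portable session format with a
    validated coordinate-frame graph, time-synchronized stream resampling,
    and a synthetic session generator with scripted ground truth so every
    stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
SystemRequirements: zlib
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
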