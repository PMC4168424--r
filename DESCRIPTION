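Package: gaitmode
Title: Locomotion Mode Recognition and Transition Prediction from Wearable Gait Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting locomotion intent from multichannel wearable
    sensor recordings (plantar-pressure insoles and inertial measurement units
    sampled at 100 Hz). Implements a two-level recognition strategy: plantar
    pressure drives a gait-phase state machine (initial double stance, single
    stance, terminal double stance, swing), and one linear discriminant
    classifier per phase recognizes six locomotion modes (standing, level
    walking, stair ascent/descent, ramp ascent/descent) from time-domain
    features of 150 ms sliding windows. Raw decision streams are smoothed by
    posterior-weighted majority voting, and locomotion transitions are scored
    by prediction time relative to the critical foot-contact moment. A
    synthetic gait simulator generates labeled multi-subject cohorts so the
    full pipeline can be trained and evaluated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
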