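Package: herdtrack
Title: Multi-Object Tracking and Geolocation of Herd Animals from UAV Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for aerial monitoring of herd animals with a small UAV:
    two-stage greedy data association with a stranding area for occlusion
    recovery, an interacting-multiple-model particle filter (IMM-PF) for
    target state estimation, pixel-to-ground line-of-sight geolocation
    through camera/IMU/geographic coordinate frames, the CLEAR-MOT and
    identity (IDF1) evaluation suite, and a synthetic aerial-herd scenario
    simulator with Markov-switched ground-plane motion, pinhole projection
    from a jittering camera, and detection corruption models. Detections
    enter as MOTChallenge-format text files; no detector is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
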