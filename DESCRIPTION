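Package: quadgait
Title: Quadrupedal Interlimb Coordination and Gait Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of quadrupedal locomotion from per-limb footfall
    events and planar marker tracks: step-cycle extraction, circular
    interlimb phase computation with lead-limb folding, control
    variability bands and altered-step classification, circular
    descriptive statistics and the two-sample Watson U2 test, unpooled
    two-proportion z tests on altered-step counts, speed-dependent gait
    classification (walk-trot, gallop, half-bound, full-bound),
    stride-speed spatiotemporal regression, intralimb two-angle
    kinematics, and a seeded von Mises synthetic gait generator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
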