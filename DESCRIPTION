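Package: scapsim
Title: Thoracoscapular Shoulder Model Simulation and Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained musculoskeletal toolkit for the human shoulder
    built around a four degree-of-freedom scapulothoracic joint in which the
    scapula glides on a thoracic ellipsoid. Provides a built-in 33-actuator
    Hill-type (rigid-tendon) muscle set with thoracoscapular and glenohumeral
    muscles, muscle-path and wrapping geometry with tendon-excursion moment
    arms, marker-based inverse kinematics, a static-optimization tracking
    controller with reserve actuators, muscle mechanical work and external
    (potential-energy) work accounting, an EMG envelope/MVC processing chain,
    and a synthetic-data generator for shrug, flexion and abduction tasks with
    and without a 2 kg hand-held mass. Reads and writes TRC, MOT/STO, CSV and
    a documented XML model subset.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    xml2,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
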