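Package: needletrack
Title: Markerless Biopsy Needle Tracking and Mixed-Reality Guidance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vision-based tracking of a biopsy needle for mixed-reality
    surgical navigation. Detects the needle line in RGB camera images using
    edge detection with metaheuristic (Grey Wolf Optimizer) threshold tuning
    and a Hough transform, lifts the line to a 3D pose from near-range depth
    point clouds, stabilises the pose with Kalman filtering and exponential
    moving averaging, registers holographic and model coordinate frames via
    paired-point fiducial markers, and provides trajectory-alignment guidance
    metrics. Includes a synthetic scene simulator with ground truth in place
    of headset hardware, plus evaluation utilities for puncture-accuracy and
    procedure-time studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: EBImage, igraph, jsonlite, png, yaml, stats, utils, withr
Suggests: testthat (>= 3.0.0), vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
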