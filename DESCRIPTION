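Package: broilertrack
Title: Individual Broiler Feeding-Time Estimation from Head Detections
Version: 1.0.0
Authors@R:
    person("Broilertrack", "Developers", email = "broilertrack@example.org",
           role = c("aut", "cre"))
Description: Estimates the feeding time of individual broiler chickens from
    per-frame head-detection bounding boxes produced by any object detector.
    Implements Euclidean-distance centroid tracking with bounded history and
    missed-frame expiry, a feeding index based on the exact intersection area
    of the head bounding box with a circular feeder region, segmentation of
    feeding frames into per-bird visits with frame-to-second conversion, an
    evaluation protocol against manually labeled ground truth (head-count,
    overall and per-visit feeding-time accuracy), and a synthetic flock
    simulator (Markov behavior model plus detector noise) so the whole
    pipeline is testable without video or a trained detector. Includes
    readers and writers for MOT-Challenge detection CSV, per-frame YOLO text
    files, scene configuration files, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
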