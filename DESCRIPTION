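Package: planargait
Title: Planar Gait Kinematics from 2D Pose Keypoints with Marker-Based
    Agreement Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for validating two-dimensional, single-camera gait
    analysis against a marker-based reference. Computes bilateral sagittal
    hip, knee and ankle joint-angle waveforms from pose-estimation keypoints
    (OpenPose BODY-25 style JSON) and from reference joint-center
    trajectories, segments gait cycles from vertical ground-reaction-force
    data using a 20 N contact threshold, extracts twelve per-cycle
    joint-angle parameters, and quantifies agreement between the two
    measurement streams with mean absolute error and parametric confidence
    intervals, the coefficient of multiple correlation, ICC(1,k) trial
    reproducibility, Pearson correlation and paired t-tests, together with
    the customary clinical interpretation bands. A planar forward-kinematics
    gait simulator with a known ground truth (keypoints, joint centers,
    double-bump vertical ground reaction forces, pixel noise and
    occlusion-driven keypoint dropout) makes the full pipeline testable
    without laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
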