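Package: poserefine
Title: Temporal Refinement of Articulated 3D Pose Sequences by
    Attention-Weighted Quaternion Averaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing refinement of noisy per-frame articulated 3D body
    pose sequences (24 joint rotations in unit-quaternion form, SMPL-style
    parameterization). A small non-local self-attention network regresses, for
    each sliding temporal window, nonnegative affinity weights that are used to
    average the window's unit quaternions joint-by-joint; the normalized
    weighted quaternion mean is a second-order approximation of the mean of 3D
    rotations, so the refined pose stays on the rotation manifold.  Includes a
    synthetic SMPL-compatible body model (kinematic tree, linear blend
    skinning, joint regression), the standard pose-sequence evaluation metrics
    (MPJPE, PA-MPJPE, MPVE, acceleration error), SLERP / learned-Gaussian /
    direct-regression baseline refiners, a keyframe-based synthetic motion
    generator with an estimator-like noise model, and a fully seeded training
    loop so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
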