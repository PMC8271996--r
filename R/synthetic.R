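# Synthetic motion: smooth ground-truth sequences from per-joint keyframe
# random walks with SLERP interpolation, and an estimator-like corruption
# model (per-frame rotational jitter plus occasional gross outlier frames,
# emulating the failure modes of video-based pose estimators under occlusion).

# Per-joint bound (radians) on the rotation step between consecutive
# keyframes; larger for limbs, small for the spine.  Order = .JOINT_NAMES.
.KEYFRAME_STEP <- c(
  pelvis = 0.30, hip.L = 0.50, hip.R = 0.50, spine1 = 0.20,
  knee.L = 0.70, knee.R = 0.70, spine2 = 0.20, ankle.L = 0.40,
  ankle.R = 0.40, spine3 = 0.20, foot.L = 0.20, foot.R = 0.20,
  neck = 0.30, collar.L = 0.20, collar.R = 0.20, head = 0.30,
  shoulder.L = 0.60, shoulder.R = 0.60, elbow.L = 0.80, elbow.R = 0.80,
  wrist.L = 0.50, wrist.R = 0.50, hand.L = 0.30, hand.R = 0.30)

.random_axis <- function(n) {
  v <- matrix(stats::rnorm(3L * n), ncol = 3L)
  v / sqrt(rowSums(v * v))
}

#' Generate a smooth ground-truth motion
#'
#' Per joint, a random walk over keyframes spaced `keyframe_gap` frames apart:
#' each keyframe rotation composes the previous one with a random-axis step
#' whose angle is uniform on `[0, step_j]`, where `step_j` is a fixed
#' humanoid-plausible per-joint bound (small for the spine, larger for elbows
#' and knees; see the package vignette).  Frames between keyframes are SLERP
#' interpolated, so the motion is piecewise-geodesic and temporally smooth.
#' The identity vector is drawn from a standard normal and fixed for the
#' sequence.  Deterministic given `seed`.
#'
#' @param n_frames Number of frames (>= 2).
#' @param template A `body_template` (validates the joint count; the motion
#'   itself is independent of shape).
#' @param keyframe_gap Frames between keyframes (default 15).
#' @param seed Integer seed.
#' @param fps Frame rate (default 30).
#' @return A `pose_sequence`.
#' @export
generate_gt_motion <- function(n_frames, template, keyframe_gap = 15L, seed = 1L,
                               fps = 30) {
  .validate_template(template)
  stopifnot(n_frames >= 2L, keyframe_gap >= 1L)
  .with_seed(seed, {
    beta <- stats::rnorm(10L)
    # keyframe grid extends past the last frame so every segment spans the
    # full gap and the per-frame angular step stays <= step_max / gap
    key_t <- seq(1L, n_frames + keyframe_gap - 1L, by = keyframe_gap)
    nk <- length(key_t)
    quats <- array(0, c(n_frames, 24L, 4L))
    for (j in 1:24) {
      step_max <- .KEYFRAME_STEP[j]
      ax <- .random_axis(nk)
      ang <- stats::runif(nk, 0, step_max)
      keys <- matrix(0, nk, 4L)
      keys[1L, ] <- axis_angle_to_quat(ang[1L] * ax[1L, ])
      for (k in seq_len(nk - 1L)) {
        keys[k + 1L, ] <- quat_multiply(keys[k, ],
                                        axis_angle_to_quat(ang[k + 1L] * ax[k + 1L, ]))
        tt <- key_t[k]:min(key_t[k + 1L], n_frames)
        quats[tt, j, ] <- .slerp_pair_path(keys[k, ], keys[k + 1L, ],
                                           (tt - key_t[k]) / keyframe_gap)
      }
    }
    pose_sequence(quats, beta = beta, fps = fps)
  })
}

#' Noise configuration for motion corruption
#'
#' @param jitter_sigma Per-joint tangent-space Gaussian scale, radians (every
#'   joint of every frame).
#' @param outlier_prob Per-frame probability of a gross outlier (all joints of
#'   the frame perturbed at `outlier_sigma`), emulating occlusion failures.
#' @param outlier_sigma Tangent-space scale of outlier perturbations, radians.
#' @param seed Integer seed driving the corruption.
#' @return A `noise_config` list.
#' @export
noise_config <- function(jitter_sigma = 0.05, outlier_prob = 0.03,
                         outlier_sigma = 0.6, seed = 1L) {
  stopifnot(jitter_sigma >= 0, outlier_sigma >= 0,
            outlier_prob >= 0, outlier_prob <= 1)
  structure(list(jitter_sigma = jitter_sigma, outlier_prob = outlier_prob,
                 outlier_sigma = outlier_sigma, seed = as.integer(seed)),
            class = "noise_config")
}

#' Corrupt a motion with estimator-like noise
#'
#' Composes every joint-local rotation with a tangent-space Gaussian
#' perturbation (axis-angle vector with i.i.d. `N(0, jitter_sigma^2)`
#' components, applied in the joint's local frame); additionally, with
#' probability `outlier_prob` per frame, every joint of that frame receives a
#' second perturbation at scale `outlier_sigma`.  The geodesic deviation of a
#' perturbed rotation equals the norm of its tangent draw.  Deterministic
#' given `cfg$seed`; with all noise scales zero the input is returned exactly.
#'
#' @param gt A ground-truth `pose_sequence`.
#' @param cfg A [noise_config()].
#' @return A corrupted `pose_sequence` (same identity vector and fps).
#' @export
corrupt_motion <- function(gt, cfg) {
  stopifnot(inherits(gt, "pose_sequence"), inherits(cfg, "noise_config"))
  if (cfg$jitter_sigma == 0 && cfg$outlier_prob == 0) return(gt)
  T_ <- n_frames(gt)
  .with_seed(cfg$seed, {
    out_frames <- stats::runif(T_) < cfg$outlier_prob
    quats <- gt$quats
    nq <- T_ * 24L
    if (cfg$jitter_sigma > 0) {
      delta <- matrix(stats::rnorm(3L * nq, sd = cfg$jitter_sigma), ncol = 3L)
      qd <- axis_angle_to_quat(delta)
      qm <- matrix(quats, nrow = nq, ncol = 4L)
      quats <- array(quat_multiply(qm, qd), c(T_, 24L, 4L))
    }
    if (any(out_frames) && cfg$outlier_sigma > 0) {
      idx <- which(out_frames)
      delta <- matrix(stats::rnorm(3L * length(idx) * 24L, sd = cfg$outlier_sigma),
                      ncol = 3L)
      qd <- axis_angle_to_quat(delta)
      sub <- quats[idx, , , drop = FALSE]
      qm <- matrix(sub, nrow = length(idx) * 24L, ncol = 4L)
      quats[idx, , ] <- array(quat_multiply(qm, qd), c(length(idx), 24L, 4L))
    }
    pose_sequence(quats, beta = gt$beta, fps = gt$fps)
  })
}

#' Build a training corpus of (noisy, ground-truth) sequence pairs
#'
#' Generates `n_sequences` ground-truth motions (seeds derived from `seed`),
#' corrupts each with `cfg` (corruption seeds also derived from `seed`), and
#' attaches a uniform chunk sampler: `sample_batch(n, n_window)` draws `n`
#' (sequence, center-frame) pairs uniformly over all valid center positions,
#' using the caller's RNG stream.
#'
#' @param n_sequences Number of sequence pairs.
#' @param n_frames Frames per sequence.
#' @param cfg A [noise_config()]; its `seed` field is overridden per sequence.
#' @param template A `body_template` (carried along for training/evaluation).
#' @param seed Integer master seed.
#' @param keyframe_gap,fps Passed to [generate_gt_motion()].
#' @return A `pose_corpus`: list with `pairs` (each `list(noisy, gt)`),
#'   `template`, and `sample_batch(n, n_window)`.
#' @export
make_training_corpus <- function(n_sequences, n_frames, cfg, template,
                                 seed = 1L, keyframe_gap = 15L, fps = 30) {
  stopifnot(n_sequences >= 1L)
  pairs <- vector("list", n_sequences)
  for (i in seq_len(n_sequences)) {
    gt <- generate_gt_motion(n_frames, template, keyframe_gap = keyframe_gap,
                             seed = seed * 10000L + 2L * i, fps = fps)
    cfg_i <- cfg
    cfg_i$seed <- seed * 10000L + 2L * i + 1L
    pairs[[i]] <- list(noisy = corrupt_motion(gt, cfg_i), gt = gt)
  }
  corpus <- list(pairs = pairs, template = template, n_frames = n_frames,
                 seed = as.integer(seed))
  corpus$sample_batch <- function(n, n_window = 17L) {
    half <- (n_window - 1L) %/% 2L
    if (n_frames < n_window) {
      stop("sequences shorter than the chunk window", call. = FALSE)
    }
    data.frame(
      sequence = sample.int(n_sequences, n, replace = TRUE),
      center = sample.int(n_frames - 2L * half, n, replace = TRUE) + half
    )
  }
  structure(corpus, class = "pose_corpus")
}
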