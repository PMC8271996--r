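# poserefine

Temporal refinement of articulated 3D human pose sequences by
attention-weighted quaternion averaging.

## What problem this solves

Video-based human mesh recovery methods (SMPL-style: identity vector
β ∈ R¹⁰, pose θ ∈ R⁷² of 24 per-joint 3D rotations) produce per-frame pose
estimates that are accurate on average but temporally noisy — small
rotational jitter everywhere, plus occasional grossly wrong frames caused by
occlusion.  `poserefine` is for researchers and engineers in human movement
analysis who need a model-agnostic post-processing step that makes such
sequences accurate *and* smooth, and a fully self-contained synthetic
benchmark to train and validate it without any external dataset or licensed
body-model asset.

## The method

For each frame, a window of N = 17 consecutive poses (as 24 unit quaternions
per frame) is refined in two steps:

1. **Weight regression** — the 96 × N quaternion chunk plus a relative
   position-index row passes through three 1-D temporal convolutions
   (kernel 3, channels 97 → 64 → 48 → 24, each with layer norm and ReLU),
   then non-local self-attention forms a pose affinity vector

       w = softmax(Hᵀ h_c),

   with `h_c` the center frame's feature column (no projections, no scaling).
2. **Weighted quaternion averaging** — per joint j, after hemisphere
   alignment to the center frame,

       q̃_j = Σᵢ wᵢ q_ij ,   q_j = q̃_j / ‖q̃_j‖ ,

   which is a second-order approximation of the chordal-L2 rotation mean.

An SMPL-compatible synthetic body model (kinematic tree, linear blend
skinning, 24 → 14 joint regression) turns poses into joints and vertices; the
L1 loss on the 14 regressed joints of the center frame trains the network
end-to-end (Adam, constant 1e-4).  Baselines: SLERP neighbor-midpoint
smoothing, a learned joint-wise Gaussian-kernel refiner, and direct pose
regression.  Metrics: MPJPE, PA-MPJPE, MPVE, acceleration error.

## Worked example

```r
library(poserefine)

template <- build_synthetic_template(seed = 1)          # synthetic SMPL-like body
corpus   <- make_training_corpus(20, 300, noise_config(), template, seed = 1001)
test     <- make_training_corpus(20, 300, noise_config(), template, seed = 2001)

fit <- train_refiner(corpus, train_config(epochs = 5, iterations_per_epoch = 200,
                                          batch_size = 32, seed = 1))
evaluate_refinement(fit, test$pairs, template, include_mpve = FALSE)
```

On one CPU core this trains in about a minute and prints:

```
  method    mpjpe pa_mpjpe mpve accel_error
 refined 19.43207 10.38592   NA    8.861105
   noisy 68.27270 35.28980   NA  182.926953
```

i.e. the refiner cuts the mean per-joint position error of the corrupted
motions from ~68 mm to ~19 mm and the acceleration error (temporal
roughness, mm/frame²) by roughly 20×, with the 8 boundary frames per side
excluded per protocol.  `refine_sequence(seq, fit$params)` applies a trained
refiner to any `pose_sequence`; `slerp_refine()` and the `"gaussian"` /
`"direct"` variants of `refiner_params()` provide the baselines, and
`compare_refiners()` builds a one-row-per-method comparison table.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/scripts/poserefine simulate --seed 1 --n-sequences 4 --out data/
Rscript inst/scripts/poserefine train --data data/ --epochs 5 --iters 200 --batch 32 --out ckpt.rds
Rscript inst/scripts/poserefine refine --checkpoint ckpt.rds --in data/seq_001_noisy.txt --out refined.txt
```

See `vignette("pose-refinement")` for the model, its assumptions, parameter
choices and known limitations.

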