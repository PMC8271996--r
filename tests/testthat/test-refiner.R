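# Refiner pipeline: positional encoding, convolutional features, affinity
# weights, chunk refinement and sliding-window sequence refinement.

make_noisy_sequence <- function(T_ = 40L, seed = 1L, jitter = 0.05,
                                outlier = 0) {
  tpl <- build_synthetic_template(1)
  gt <- generate_gt_motion(T_, tpl, seed = seed)
  list(gt = gt,
       noisy = corrupt_motion(gt, noise_config(jitter, outlier, 0.6,
                                               seed = seed + 100L)))
}

test_that("positional encoding stacks quaternions with the index ramp", {
  seqs <- make_noisy_sequence(30)
  chunk <- pose_chunk(seqs$noisy, 15L, 17L)
  enc <- encode_positions(chunk)
  expect_identical(dim(enc), c(97L, 17L))
  expect_equal(enc[97, ], seq(-8, 8))
  chunk3 <- pose_chunk(seqs$noisy, 15L, 3L)
  expect_equal(encode_positions(chunk3)[97, ], c(-1, 0, 1))
  # stripping the index row recovers the input quaternions exactly
  for (n in 1:17) {
    expect_identical(matrix(enc[1:96, n], 4L), t(chunk$quats[n, , ]))
  }
})

test_that("feature extraction matches a naive convolution oracle", {
  params <- refiner_params("attention", n_window = 17L, seed = 5)
  seqs <- make_noisy_sequence(30)
  enc <- encode_positions(pose_chunk(seqs$noisy, 15L, 17L))
  H <- extract_features(enc, params)
  expect_identical(dim(H), c(24L, 17L))
  X <- enc
  for (l in 1:3) X <- naive_conv_block(X, params$layers[[l]])
  expect_equal(H, X, tolerance = 1e-6)
})

test_that("affinity weights are the softmax of center-frame dot products", {
  # identical columns give uniform weights
  H <- matrix(rep(rnorm(24), 9), 24, 9)
  expect_equal(compute_affinity(H), rep(1 / 9, 9), tolerance = 1e-12)
  set.seed(31)
  H <- matrix(rnorm(24 * 9), 24, 9)
  w <- compute_affinity(H)
  expect_true(all(w > 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  logits <- drop(t(H) %*% H[, 5])
  expect_equal(w, exp(logits) / sum(exp(logits)), tolerance = 1e-9)
})

test_that("chunk refinement equals the joint-wise weighted quaternion mean", {
  params <- refiner_params("attention", seed = 6)
  seqs <- make_noisy_sequence(40)
  chunk <- pose_chunk(seqs$noisy, 20L, 17L)
  out <- refine_chunk(chunk, params)
  w <- compute_affinity(extract_features(encode_positions(chunk), params))
  for (j in 1:24) {
    m <- weighted_quat_mean(matrix(chunk$quats[, j, ], ncol = 4L), w)
    expect_equal(out[j, ], m, tolerance = 1e-12)
  }
})

test_that("a temporally constant chunk is a fixed point of refinement", {
  for (variant in c("attention", "gaussian")) {
    params <- refiner_params(variant, seed = 7)
    seq_const <- make_constant_sequence(17L, seed = 8)
    chunk <- pose_chunk(seq_const, 9L, 17L)
    out <- refine_chunk(chunk, params)
    expect_equal(out, chunk$quats[9L, , ], tolerance = 1e-12)
  }
})

test_that("untrained refinement stays inside the window's rotation hull", {
  params <- refiner_params("attention", seed = 9)
  set.seed(32)
  # nearby rotations: tight cluster per joint
  quats <- array(0, c(17, 24, 4))
  base <- rand_unit_quats(24)
  for (t in 1:17) {
    for (j in 1:24) quats[t, j, ] <- rand_quats_near(1, base[j, ], 0.15)
  }
  s <- pose_sequence(quats)
  chunk <- pose_chunk(s, 9L, 17L)
  out <- refine_chunk(chunk, params)
  for (j in 1:24) {
    qin <- matrix(chunk$quats[, j, ], ncol = 4L)
    max_pair <- max(outer(1:17, 1:17, Vectorize(function(a, b) {
      quat_geodesic(qin[a, ], qin[b, ])
    })))
    d_out <- max(quat_geodesic(matrix(out[j, ], 1, 4)[rep(1, 17), ], qin))
    expect_lte(d_out, max_pair + 1e-9)
    # and within the dispersion radius around the window's chordal mean
    ctr <- eig_chordal_mean(qin, rep(1 / 17, 17))
    radius <- max(quat_geodesic(qin, matrix(ctr, 17, 4, byrow = TRUE)))
    expect_lte(quat_geodesic(out[j, ], ctr), radius + 1e-9)
  }
})

test_that("sliding-window refinement follows the boundary protocol", {
  params <- refiner_params("attention", seed = 10)
  seqs <- make_noisy_sequence(20)
  refined <- refine_sequence(seqs$noisy, params)
  expect_identical(n_frames(refined), 20L)
  # T = 20, N = 17: frames 9..12 refined, 8 at each end copied through
  changed <- vapply(1:20, function(t) {
    !isTRUE(all.equal(refined$quats[t, , ], seqs$noisy$quats[t, , ],
                      tolerance = 0))
  }, TRUE)
  expect_identical(which(changed), 9:12)
  expect_identical(refined$quats[1:8, , ], seqs$noisy$quats[1:8, , ])
  expect_identical(refined$quats[13:20, , ], seqs$noisy$quats[13:20, , ])
  expect_identical(refined$beta, seqs$noisy$beta)
  expect_error(refine_sequence(make_noisy_sequence(10)$noisy, params),
               class = "sequence_too_short")
})

test_that("refined sequences keep valid unit quaternions and are bit-stable", {
  for (variant in c("attention", "gaussian", "direct")) {
    params <- refiner_params(variant, seed = 11)
    seqs <- make_noisy_sequence(25, seed = 3, outlier = 0.1)
    r1 <- refine_sequence(seqs$noisy, params)
    r2 <- refine_sequence(seqs$noisy, params)
    expect_identical(r1, r2)
    nrm <- sqrt(apply(r1$quats^2, c(1, 2), sum))
    expect_lt(max(abs(nrm - 1)), 1e-6)
  }
})

test_that("batching the sequence windows does not change the result", {
  params <- refiner_params("attention", seed = 12)
  seqs <- make_noisy_sequence(60)
  expect_equal(refine_sequence(seqs$noisy, params, block = 7L),
               refine_sequence(seqs$noisy, params, block = 512L),
               tolerance = 1e-12)
})

test_that("parameter gradients of all variants match finite differences", {
  pr <- asNamespace("poserefine")
  set.seed(33)
  B <- 2L; N <- 5L
  Q <- array(t(rand_unit_quats(24 * N * B)), c(4, 24, N, B))
  dY <- array(rnorm(4 * 24 * B), c(4, 24, B)) * 0.1
  eps <- 1e-6
  for (variant in c("attention", "gaussian", "direct")) {
    params <- refiner_params(variant, n_window = N, hidden = c(8L, 6L), seed = 13)
    fw <- pr$.variant_forward(Q, params)
    gr <- pr$.grads_flatten(pr$.variant_backward(fw, dY, params))
    flat <- pr$.params_flatten(params)
    lossf <- function(fl) {
      sum(pr$.variant_forward(Q, pr$.params_unflatten(params, fl))$Y * dY)
    }
    for (nm in names(flat)) {
      idx <- sample(length(flat[[nm]]), min(4, length(flat[[nm]])))
      for (i in idx) {
        fl <- flat; fl[[nm]][i] <- fl[[nm]][i] + eps; up <- lossf(fl)
        fl <- flat; fl[[nm]][i] <- fl[[nm]][i] - eps; dn <- lossf(fl)
        expect_equal(gr[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-3)
      }
    }
  }
})
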