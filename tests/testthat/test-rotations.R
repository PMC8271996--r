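# Rotation algebra: conversions, distances, SLERP and the weighted
# quaternion mean, validated against independent oracles.

test_that("axis-angle to quaternion handles identity and half-turn exactly", {
  expect_equal(axis_angle_to_quat(c(0, 0, 0)), c(1, 0, 0, 0))
  expect_equal(axis_angle_to_quat(c(0, 0, pi)), c(0, 0, 0, 1),
               tolerance = 1e-15)
})

test_that("axis-angle conversion matches the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  set.seed(11)
  for (i in 1:50) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    v <- runif(1, 0.1, 3) * ax
    M <- quat_to_matrix(axis_angle_to_quat(v))
    expect_lt(max(abs(M - expm_rotation(v))), 1e-9)
  }
})

test_that("quaternion to axis-angle inverts the forward map", {
  expect_equal(quat_to_axis_angle(c(1, 0, 0, 0)), c(0, 0, 0))
  expect_equal(quat_to_axis_angle(c(0, 1, 0, 0)), c(pi, 0, 0))
  set.seed(12)
  q <- rand_unit_quats(1000)
  rt <- axis_angle_to_quat(quat_to_axis_angle(q))
  expect_lt(max(quat_geodesic(q, rt)), 1e-9)
  ang <- sqrt(rowSums(quat_to_axis_angle(q)^2))
  expect_true(all(ang >= 0 & ang <= pi + 1e-12))
  expect_error(quat_to_axis_angle(c(1, 1, 0, 0)), "unit")
})

test_that("tiny-angle conversions stay accurate through the series branch", {
  v <- c(3e-9, -2e-9, 1e-9)
  q <- axis_angle_to_quat(v)
  expect_equal(sum(q^2), 1, tolerance = 1e-15)
  expect_equal(quat_to_axis_angle(q), v, tolerance = 1e-20)
})

test_that("quaternion to matrix is a homomorphism onto SO(3)", {
  expect_equal(quat_to_matrix(c(1, 0, 0, 0)), diag(3))
  expect_equal(quat_to_matrix(c(0, 0, 0, 1)), diag(c(-1, -1, 1)))
  set.seed(13)
  for (i in 1:30) {
    q1 <- drop(rand_unit_quats(1)); q2 <- drop(rand_unit_quats(1))
    M12 <- quat_to_matrix(quat_multiply(q1, q2))
    expect_lt(max(abs(M12 - quat_to_matrix(q1) %*% quat_to_matrix(q2))), 1e-9)
    M <- quat_to_matrix(q1)
    expect_lt(max(abs(crossprod(M) - diag(3))), 1e-9)
    expect_equal(det(M), 1, tolerance = 1e-9)
  }
})

test_that("weighted quaternion mean respects convexity and one-hot weights", {
  set.seed(14)
  q <- drop(rand_unit_quats(1))
  quats <- matrix(q, 5, 4, byrow = TRUE)
  w <- runif(5); w <- w / sum(w)
  expect_equal(weighted_quat_mean(quats, w), quat_canonical(q),
               tolerance = 1e-12)
  quats <- rand_unit_quats(5)
  for (k in 1:5) {
    w <- numeric(5); w[k] <- 1
    expect_equal(weighted_quat_mean(quats, w), quat_canonical(quats[k, ]),
                 tolerance = 1e-12)
  }
})

test_that("weighted mean approximates the eigenvector chordal-L2 mean", {
  set.seed(15)
  for (i in 1:20) {
    base <- drop(rand_unit_quats(1))
    quats <- rand_quats_near(7, base, 0.2)
    w <- rep(1 / 7, 7)
    m <- weighted_quat_mean(quats, w)
    expect_lt(quat_geodesic(m, eig_chordal_mean(quats, w)), 1e-3)
  }
})

test_that("weighted mean is sign-invariant and left-equivariant", {
  set.seed(16)
  base <- drop(rand_unit_quats(1))
  quats <- rand_quats_near(9, base, 0.4)
  w <- runif(9); w <- w / sum(w)
  m0 <- weighted_quat_mean(quats, w)
  flipped <- quats
  flipped[c(2, 5, 7), ] <- -flipped[c(2, 5, 7), ]
  expect_equal(weighted_quat_mean(flipped, w), m0, tolerance = 1e-12)
  g <- drop(rand_unit_quats(1))
  mg <- weighted_quat_mean(quat_multiply(matrix(g, 9, 4, byrow = TRUE), quats), w)
  expect_lt(quat_geodesic(mg, quat_multiply(g, m0)), 1e-9)
})

test_that("weighted mean rejects bad weights and degenerate averages", {
  quats <- rand_unit_quats(3)
  expect_error(weighted_quat_mean(quats, c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(weighted_quat_mean(quats, c(-0.2, 0.6, 0.6)), "nonnegative")
  # after alignment to element 1, elements 2 and 3 cancel exactly
  anti <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 1), c(0, 0, 0, -1))
  expect_error(weighted_quat_mean(anti, c(0, 0.5, 0.5), ref_index = 1L),
               class = "degenerate_average")
})

test_that("slerp interpolates geodesically with hemisphere alignment", {
  set.seed(17)
  q <- drop(rand_unit_quats(1))
  expect_equal(quat_slerp(q, q, 0.7), q)
  mid <- quat_slerp(c(1, 0, 0, 0), axis_angle_to_quat(c(0, 0, pi / 2)), 0.5)
  expect_equal(mid, axis_angle_to_quat(c(0, 0, pi / 4)), tolerance = 1e-12)
  expect_equal(quat_slerp(q, -q, 0.3), q, tolerance = 1e-12)
  # endpoints
  q2 <- drop(rand_unit_quats(1))
  expect_lt(quat_geodesic(quat_slerp(q, q2, 0), q), 1e-12)
  expect_lt(quat_geodesic(quat_slerp(q, q2, 1), q2), 1e-12)
  # small-angle agreement with the two-point weighted mean
  for (i in 1:10) {
    base <- drop(rand_unit_quats(1))
    pair <- rand_quats_near(2, base, 0.05)
    s <- quat_slerp(pair[1, ], pair[2, ], 0.5)
    m <- weighted_quat_mean(pair, c(0.5, 0.5), ref_index = 1L)
    expect_lt(quat_geodesic(s, m), 1e-4)
  }
})

test_that("constant speed of slerp along the geodesic", {
  set.seed(18)
  q1 <- drop(rand_unit_quats(1)); q2 <- drop(rand_unit_quats(1))
  total <- quat_geodesic(q1, q2)
  ts <- seq(0, 1, by = 0.25)
  pts <- t(vapply(ts, function(t) quat_slerp(q1, q2, t), numeric(4)))
  steps <- quat_geodesic(pts[-5, ], pts[-1, ])
  expect_equal(steps, rep(total / 4, 4), tolerance = 1e-9)
})

test_that("chordal squared distance equals 4(1 - cos theta)", {
  R <- rand_rotation()
  expect_equal(chordal_sq_distance(R, R), 0)
  expect_equal(chordal_sq_distance(diag(3), quat_to_matrix(c(0, 1, 0, 0))), 8)
  set.seed(19)
  for (i in 1:20) {
    q1 <- drop(rand_unit_quats(1)); q2 <- drop(rand_unit_quats(1))
    th <- quat_geodesic(q1, q2)
    d <- chordal_sq_distance(quat_to_matrix(q1), quat_to_matrix(q2))
    expect_equal(d, 4 * (1 - cos(th)), tolerance = 1e-9)
  }
})

test_that("canonical sign flips exactly the negative-scalar hemisphere", {
  set.seed(20)
  q <- rand_unit_quats(200)
  qc <- quat_canonical(q)
  expect_true(all(qc[, 1] >= 0))
  expect_lt(max(quat_geodesic(q, qc)), 1e-12)
})
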