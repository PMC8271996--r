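# Synthetic body template, forward kinematics, skinning and joint regression.

test_that("template construction is deterministic and well formed", {
  t1 <- build_synthetic_template(7)
  t2 <- build_synthetic_template(7)
  expect_identical(t1, t2)
  t3 <- build_synthetic_template(8)
  expect_false(identical(t1$vertex_template, t3$vertex_template))
  expect_identical(dim(t1$skinning_weights), c(500L, 24L))
  expect_equal(rowSums(t1$skinning_weights), rep(1, 500), tolerance = 1e-6)
  expect_true(all(t1$skinning_weights >= 0))
  # single-rooted tree with parents preceding children
  expect_identical(t1$parent_index[1], 0L)
  expect_true(all(t1$parent_index[-1] < seq(2, 24)))
  expect_equal(rowSums(t1$joint_regressor_14), rep(1, 14))
  t4 <- build_synthetic_template(7, n_vertices = 120)
  expect_identical(dim(t4$skinning_weights), c(120L, 24L))
})

test_that("shape skeleton is linear in the identity vector", {
  tpl <- build_synthetic_template(1)
  expect_equal(shape_skeleton(tpl, rep(0, 10)), tpl$rest_offsets)
  set.seed(21)
  beta <- rnorm(10)
  d1 <- shape_skeleton(tpl, beta) - tpl$rest_offsets
  d2 <- shape_skeleton(tpl, 2 * beta) - tpl$rest_offsets
  expect_equal(d2, 2 * d1)
  expect_equal(d1, matrix(tpl$shape_basis %*% beta, 24, 3))
})

test_that("identity pose reproduces cumulative rest offsets", {
  tpl <- build_synthetic_template(1)
  pose <- matrix(rep(c(1, 0, 0, 0), 24), 24, 4, byrow = TRUE)
  fk <- forward_kinematics(pose, tpl)
  expect_equal(fk$joints, rest_joints(tpl), tolerance = 1e-12)
  for (j in 1:24) expect_equal(fk$rotations[, , j], diag(3))
})

test_that("rotating only the root rigidly rotates every joint", {
  tpl <- build_synthetic_template(2)
  set.seed(22)
  beta <- rnorm(10)
  pose <- matrix(rep(c(1, 0, 0, 0), 24), 24, 4, byrow = TRUE)
  rootq <- drop(rand_unit_quats(1))
  pose_rot <- pose
  pose_rot[1, ] <- rootq
  base <- forward_kinematics(pose, tpl, beta)$joints
  rot <- forward_kinematics(pose_rot, tpl, beta)$joints
  R <- quat_to_matrix(rootq)
  expect_equal(rot, base %*% t(R), tolerance = 1e-9)
})

test_that("a mid-chain rotation matches the hand-computed rigid transform", {
  tpl <- build_synthetic_template(1)
  # chain pelvis(1) -> hip.L(2) -> knee.L(5) -> ankle.L(8), rotate the hip 90
  # degrees about x: descendants pivot rigidly about the hip joint
  pose <- matrix(rep(c(1, 0, 0, 0), 24), 24, 4, byrow = TRUE)
  pose[2, ] <- axis_angle_to_quat(c(pi / 2, 0, 0))
  fk <- forward_kinematics(pose, tpl)
  jr <- rest_joints(tpl)
  R <- quat_to_matrix(pose[2, ])
  for (j in c(5L, 8L, 11L)) {
    expect_equal(fk$joints[j, ], jr[2, ] + drop(R %*% (jr[j, ] - jr[2, ])),
                 tolerance = 1e-9)
  }
  # joints off that subtree stay at rest
  expect_equal(fk$joints[3, ], jr[3, ])
  expect_equal(fk$joints[24, ], jr[24, ])
})

test_that("forward kinematics matches the scalar-loop oracle", {
  tpl <- build_synthetic_template(3)
  set.seed(23)
  beta <- rnorm(10)
  pose <- rand_unit_quats(24)
  fk <- forward_kinematics(pose, tpl, beta)
  oracle <- naive_fk(pose, shape_skeleton(tpl, beta), tpl$parent_index)
  expect_equal(fk$joints, oracle$joints, tolerance = 1e-9)
  for (j in 1:24) {
    expect_equal(fk$rotations[, , j], oracle$rotations[[j]], tolerance = 1e-9)
  }
})

test_that("skinning reproduces the template at identity and the naive LBS", {
  tpl <- build_synthetic_template(4, n_vertices = 80)
  pose_id <- matrix(rep(c(1, 0, 0, 0), 24), 24, 4, byrow = TRUE)
  set.seed(24)
  beta <- rnorm(10)
  fk_id <- forward_kinematics(pose_id, tpl, beta)
  expect_equal(skin_vertices(fk_id, tpl, beta), tpl$vertex_template,
               tolerance = 1e-9)
  pose <- rand_unit_quats(24)
  fk <- forward_kinematics(pose, tpl, beta)
  expect_equal(skin_vertices(fk, tpl, beta), naive_lbs(fk, tpl, beta),
               tolerance = 1e-9)
})

test_that("a one-hot skinned vertex moves rigidly with its joint", {
  tpl <- build_synthetic_template(5, n_vertices = 60)
  tpl$skinning_weights[1, ] <- 0
  tpl$skinning_weights[1, 20] <- 1
  set.seed(25)
  pose <- rand_unit_quats(24)
  fk <- forward_kinematics(pose, tpl)
  jr <- rest_joints(tpl)
  v <- skin_vertices(fk, tpl)[1, ]
  expected <- drop(fk$rotations[, , 20] %*%
                     (tpl$vertex_template[1, ] - jr[20, ])) + fk$joints[20, ]
  expect_equal(v, expected, tolerance = 1e-9)
})

test_that("FK plus skinning is rigid-equivariant under a root rotation", {
  tpl <- build_synthetic_template(6, n_vertices = 60)
  set.seed(26)
  pose <- rand_unit_quats(24)
  rootq <- drop(rand_unit_quats(1))
  pose_rot <- pose
  pose_rot[1, ] <- quat_multiply(rootq, pose[1, ])
  R <- quat_to_matrix(rootq)
  v0 <- skin_vertices(forward_kinematics(pose, tpl), tpl)
  v1 <- skin_vertices(forward_kinematics(pose_rot, tpl), tpl)
  expect_equal(v1, v0 %*% t(R), tolerance = 1e-6)
})

test_that("joint regression is the documented fixed linear map", {
  tpl <- build_synthetic_template(1)
  jr <- rest_joints(tpl)
  sel <- c(9, 6, 3, 2, 5, 8, 22, 20, 18, 17, 19, 21, 13, 16)
  expect_equal(regress_joints(jr, tpl), jr[sel, ], ignore_attr = TRUE)
  set.seed(27)
  X <- matrix(rnorm(72), 24, 3)
  expect_equal(regress_joints(X, tpl), tpl$joint_regressor_14 %*% X)
  # affine map with convex rows commutes with rigid transforms
  R <- rand_rotation(); tr <- c(10, -5, 3)
  Xr <- X %*% t(R) + matrix(tr, 24, 3, byrow = TRUE)
  expect_equal(regress_joints(Xr, tpl),
               regress_joints(X, tpl) %*% t(R) + matrix(tr, 14, 3, byrow = TRUE),
               tolerance = 1e-9)
  # vertices route: regressor_24 then regressor_14
  Vx <- matrix(rnorm(tpl$n_vertices * 3), ncol = 3)
  expect_equal(regress_joints(Vx, tpl),
               tpl$joint_regressor_14 %*% (tpl$joint_regressor_24 %*% Vx))
})

test_that("batched FK gradients agree with finite differences", {
  tpl <- build_synthetic_template(1)
  set.seed(28)
  B <- 2L
  Q <- array(t(rand_unit_quats(24 * B)), c(4, 24, B))
  offs <- array(t(tpl$rest_offsets), c(3, 24, B))
  fwd <- poserefine:::.fk_batch(Q, offs, tpl$parent_index)
  dX <- array(rnorm(3 * 24 * B), c(3, 24, B))
  dQ <- poserefine:::.fk_batch_backward(fwd, dX)
  f <- function(Qv) {
    sum(poserefine:::.fk_batch(array(Qv, c(4, 24, B)), offs,
                               tpl$parent_index)$X * dX)
  }
  eps <- 1e-6
  idx <- sample(length(Q), 25)
  for (i in idx) {
    Qp <- Q; Qp[i] <- Qp[i] + eps
    Qm <- Q; Qm[i] <- Qm[i] - eps
    num <- (f(Qp) - f(Qm)) / (2 * eps)
    expect_equal(dQ[i], num, tolerance = 1e-4)
  }
})

test_that("templates assemble from raw arrays with invariant checks", {
  syn <- build_synthetic_template(2, n_vertices = 60)
  tpl <- body_template_from_arrays(syn$parent_index, syn$rest_offsets,
                                   syn$vertex_template, syn$skinning_weights,
                                   syn$joint_regressor_24, syn$shape_basis)
  pose <- rand_unit_quats(24)
  expect_equal(forward_kinematics(pose, tpl)$joints,
               forward_kinematics(pose, syn)$joints)
  bad <- syn$skinning_weights
  bad[1, ] <- bad[1, ] * 2
  expect_error(body_template_from_arrays(syn$parent_index, syn$rest_offsets,
                                         syn$vertex_template, bad,
                                         syn$joint_regressor_24),
               "sum to 1")
})
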