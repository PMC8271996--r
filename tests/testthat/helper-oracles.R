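# Independent brute-force oracles used to validate the implementation paths.

rand_unit_quats <- function(n) {
  m <- matrix(stats::rnorm(4L * n), ncol = 4L)
  m / sqrt(rowSums(m * m))
}

rand_rotation <- function() quat_to_matrix(drop(rand_unit_quats(1L)))

# quaternions within geodesic angle <= theta of a base rotation
rand_quats_near <- function(n, base, theta) {
  t(vapply(seq_len(n), function(i) {
    ax <- stats::rnorm(3L); ax <- ax / sqrt(sum(ax^2))
    drop(quat_multiply(base, axis_angle_to_quat(stats::runif(1L, 0, theta) * ax)))
  }, numeric(4L)))
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3L, 3L)
}

# matrix exponential of the skew form of an axis-angle vector (Matrix pkg)
expm_rotation <- function(v) {
  as.matrix(Matrix::expm(Matrix::Matrix(skew3(v))))
}

# chordal-L2 rotation mean: leading eigenvector of the weighted quaternion
# outer-product matrix
eig_chordal_mean <- function(quats, weights) {
  M <- matrix(0, 4L, 4L)
  for (i in seq_len(nrow(quats))) {
    M <- M + weights[i] * tcrossprod(quats[i, ])
  }
  quat_canonical(eigen(M, symmetric = TRUE)$vectors[, 1L])
}

# naive conv(k=3, zero pad) + layer norm + ReLU on a single (C x N) matrix
naive_conv_block <- function(X, layer, eps = 1e-5) {
  W <- layer$W                       # (out, in, 3)
  nout <- dim(W)[1L]; N <- ncol(X)
  Z <- matrix(0, nout, N)
  Xp <- cbind(0, X, 0)
  for (o in seq_len(nout)) for (t in seq_len(N)) {
    acc <- layer$b[o]
    for (k in 1:3) acc <- acc + sum(W[o, , k] * Xp[, t + k - 1L])
    Z[o, t] <- acc
  }
  out <- matrix(0, nout, N)
  for (t in seq_len(N)) {
    z <- Z[, t]
    xh <- (z - mean(z)) / sqrt(mean((z - mean(z))^2) + eps)
    out[, t] <- pmax(layer$g * xh + layer$be, 0)
  }
  out
}

# scalar-loop forward kinematics over the 24-joint tree
naive_fk <- function(pose, offsets, parents) {
  G <- vector("list", 24L)
  X <- matrix(0, 24L, 3L)
  for (j in 1:24) {
    Rj <- quat_to_matrix(pose[j, ])
    if (parents[j] == 0L) {
      G[[j]] <- Rj
    } else {
      p <- parents[j]
      G[[j]] <- G[[p]] %*% Rj
      X[j, ] <- X[p, ] + drop(G[[p]] %*% offsets[j, ])
    }
  }
  list(joints = X, rotations = G)
}

# per-vertex loop linear blend skinning
naive_lbs <- function(fk, template, beta) {
  jr <- rest_joints(template, beta)
  V <- template$n_vertices
  out <- matrix(0, V, 3L)
  for (v in seq_len(V)) {
    acc <- c(0, 0, 0)
    for (j in 1:24) {
      w <- template$skinning_weights[v, j]
      if (w > 0) {
        acc <- acc + w * (drop(fk$rotations[, , j] %*%
                                 (template$vertex_template[v, ] - jr[j, ])) +
                            fk$joints[j, ])
      }
    }
    out[v, ] <- acc
  }
  out
}

# Horn's quaternion absolute-orientation method (independent of the SVD
# Procrustes implementation): similarity alignment of X onto Y
horn_align <- function(X, Y) {
  mux <- colMeans(X); muy <- colMeans(Y)
  Xc <- sweep(X, 2L, mux); Yc <- sweep(Y, 2L, muy)
  S <- t(Xc) %*% Yc
  N4 <- matrix(0, 4L, 4L)
  N4[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N4[1, 2] <- N4[2, 1] <- S[2, 3] - S[3, 2]
  N4[1, 3] <- N4[3, 1] <- S[3, 1] - S[1, 3]
  N4[1, 4] <- N4[4, 1] <- S[1, 2] - S[2, 1]
  N4[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N4[2, 3] <- N4[3, 2] <- S[1, 2] + S[2, 1]
  N4[2, 4] <- N4[4, 2] <- S[3, 1] + S[1, 3]
  N4[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N4[3, 4] <- N4[4, 3] <- S[2, 3] + S[3, 2]
  N4[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N4, symmetric = TRUE)$vectors[, 1L]
  R <- quat_to_matrix(q / sqrt(sum(q^2)))
  # row-vector convention: x_aligned = x R^T
  Xr <- Xc %*% t(R)
  s <- sum(Xr * Yc) / sum(Xc * Xc)
  sweep(s * Xr, 2L, muy, "+")
}

# random pose sequence of nearly-constant rotations (for hull/window tests)
make_constant_sequence <- function(T_ = 20L, seed = 1L, fps = 30) {
  set.seed(seed)
  frame <- rand_unit_quats(24L)
  quats <- array(0, c(T_, 24L, 4L))
  for (t in seq_len(T_)) quats[t, , ] <- frame
  pose_sequence(quats, fps = fps)
}
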