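# Internal batched rigid-body kernels.  Rotations are stored as (3, 3, B)
# arrays (one 3x3 matrix per batch element) and positions as 3 x B matrices;
# all kernels are written as componentwise vector arithmetic so a whole batch
# (training chunks, or every frame of a sequence) moves through forward
# kinematics and its gradient without per-sample R loops.

.bmm <- function(A, B) {
  C <- array(0, dim(A))
  for (i in 1:3) for (k in 1:3) {
    C[i, k, ] <- A[i, 1, ] * B[1, k, ] + A[i, 2, ] * B[2, k, ] + A[i, 3, ] * B[3, k, ]
  }
  C
}

.btr <- function(A) aperm(A, c(2L, 1L, 3L))

# (3,3,B) applied to (3,B) -> (3,B)
.bvm <- function(A, v) {
  out <- matrix(0, 3L, ncol(v))
  out[1L, ] <- A[1, 1, ] * v[1, ] + A[1, 2, ] * v[2, ] + A[1, 3, ] * v[3, ]
  out[2L, ] <- A[2, 1, ] * v[1, ] + A[2, 2, ] * v[2, ] + A[2, 3, ] * v[3, ]
  out[3L, ] <- A[3, 1, ] * v[1, ] + A[3, 2, ] * v[2, ] + A[3, 3, ] * v[3, ]
  out
}

# reshape helpers: cheap dim<- instead of matrix() in hot loops
.m4 <- function(x, B) { dim(x) <- c(4L, B); x }
.m3 <- function(x, B) { dim(x) <- c(3L, B); x }
.mC <- function(x, nr) { dim(x) <- c(nr, length(x) %/% nr); x }

# outer products u v^T, (3,B) x (3,B) -> (3,3,B)
.bouter <- function(u, v) {
  C <- array(0, c(3L, 3L, ncol(u)))
  for (i in 1:3) for (k in 1:3) C[i, k, ] <- u[i, ] * v[k, ]
  C
}

# (4,B) unit quaternions -> (3,3,B) rotation matrices
.quat_to_matrix_batch <- function(Q) {
  w <- Q[1, ]; x <- Q[2, ]; y <- Q[3, ]; z <- Q[4, ]
  R <- array(0, c(3L, 3L, length(w)))
  R[1, 1, ] <- 1 - 2 * (y * y + z * z)
  R[1, 2, ] <- 2 * (x * y - w * z)
  R[1, 3, ] <- 2 * (x * z + w * y)
  R[2, 1, ] <- 2 * (x * y + w * z)
  R[2, 2, ] <- 1 - 2 * (x * x + z * z)
  R[2, 3, ] <- 2 * (y * z - w * x)
  R[3, 1, ] <- 2 * (x * z - w * y)
  R[3, 2, ] <- 2 * (y * z + w * x)
  R[3, 3, ] <- 1 - 2 * (x * x + y * y)
  R
}

# Gradient of the quadratic quaternion->matrix map: given unit quaternions
# Q (4,B) and upstream gradients G = dL/dR (3,3,B), returns dL/dQ (4,B).
.dmat_dquat <- function(Q, G) {
  w <- Q[1, ]; x <- Q[2, ]; y <- Q[3, ]; z <- Q[4, ]
  g11 <- G[1, 1, ]; g12 <- G[1, 2, ]; g13 <- G[1, 3, ]
  g21 <- G[2, 1, ]; g22 <- G[2, 2, ]; g23 <- G[2, 3, ]
  g31 <- G[3, 1, ]; g32 <- G[3, 2, ]; g33 <- G[3, 3, ]
  dw <- 2 * (-z * g12 + y * g13 + z * g21 - x * g23 - y * g31 + x * g32)
  dx <- 2 * (y * g12 + z * g13 + y * g21 - 2 * x * g22 - w * g23 +
               z * g31 + w * g32 - 2 * x * g33)
  dy <- 2 * (-2 * y * g11 + x * g12 + w * g13 + x * g21 + z * g23 -
               w * g31 + z * g32 - 2 * y * g33)
  dz <- 2 * (-2 * z * g11 - w * g12 + x * g13 + w * g21 - 2 * z * g22 +
               y * g23 + x * g31 + y * g32)
  rbind(dw, dx, dy, dz, deparse.level = 0)
}

# Batched forward kinematics over the 24-joint tree.
#   Q    (4, 24, B)  local joint rotations (unit quaternions)
#   offs (3, 24, B)  shaped parent-relative rest offsets, mm
# Returns local/global rotation matrices (lists of (3,3,B)) and joint
# positions (3, 24, B), root at the origin.
.fk_batch <- function(Q, offs, parents) {
  B <- dim(Q)[3L]
  Rl <- vector("list", 24L)
  Gl <- vector("list", 24L)
  X <- array(0, c(3L, 24L, B))
  for (j in 1:24) Rl[[j]] <- .quat_to_matrix_batch(.m4(Q[, j, ], B))
  Gl[[1L]] <- Rl[[1L]]
  for (j in 2:24) {
    p <- parents[j]
    Gl[[j]] <- .bmm(Gl[[p]], Rl[[j]])
    X[, j, ] <- .m3(X[, p, ], B) + .bvm(Gl[[p]], .m3(offs[, j, ], B))
  }
  list(R = Rl, G = Gl, X = X, Q = Q, offs = offs, parents = parents)
}

# Reverse-mode gradient of .fk_batch: given dL/dX (3, 24, B) (and optionally
# dL/dG per joint), returns dL/dQ (4, 24, B).  Children have larger indices
# than their parents, so a single descending sweep accumulates everything.
.fk_batch_backward <- function(fwd, dX, dG_extra = NULL) {
  B <- dim(fwd$X)[3L]
  parents <- fwd$parents
  zero33 <- array(0, c(3L, 3L, B))
  dG <- if (is.null(dG_extra)) rep(list(zero33), 24L) else dG_extra
  dXl <- vector("list", 24L)
  for (j in 1:24) dXl[[j]] <- .m3(dX[, j, ], B)
  dQ <- array(0, c(4L, 24L, B))
  for (j in 24:2) {
    p <- parents[j]
    oj <- .m3(fwd$offs[, j, ], B)
    dXl[[p]] <- dXl[[p]] + dXl[[j]]
    dG[[p]] <- dG[[p]] + .bouter(dXl[[j]], oj)
    dRj <- .bmm(.btr(fwd$G[[p]]), dG[[j]])
    dG[[p]] <- dG[[p]] + .bmm(dG[[j]], .btr(fwd$R[[j]]))
    dQ[, j, ] <- .dmat_dquat(.m4(fwd$Q[, j, ], B), dRj)
  }
  dQ[, 1, ] <- .dmat_dquat(.m4(fwd$Q[, 1, ], B), dG[[1L]])
  dQ
}
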