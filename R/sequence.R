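# Pose-sequence and pose-chunk containers.

#' Construct a pose sequence
#'
#' A pose sequence holds `T` frames of 24 joint-local rotations in
#' unit-quaternion form (scalar-first, canonical sign), a 10-component
#' identity/shape vector, and a frame rate.
#'
#' @param quats A `T x 24 x 4` array of unit quaternions (frame, joint,
#'   component).
#' @param beta Length-10 identity vector (default zeros).
#' @param fps Frames per second (default 30).
#' @return A `pose_sequence` object.
#' @export
pose_sequence <- function(quats, beta = rep(0, 10), fps = 30) {
  stopifnot(is.array(quats), length(dim(quats)) == 3L,
            dim(quats)[2L] == 24L, dim(quats)[3L] == 4L, dim(quats)[1L] >= 1L,
            length(beta) == 10L, is.finite(fps), fps > 0)
  nrm <- sqrt(apply(quats^2, c(1L, 2L), sum))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("all joint rotations must be unit quaternions (within 1e-6)", call. = FALSE)
  }
  T_ <- dim(quats)[1L]
  qm <- quat_canonical(matrix(quats, nrow = T_ * 24L, ncol = 4L))
  quats <- array(qm, c(T_, 24L, 4L))
  structure(list(quats = quats, beta = as.numeric(beta), fps = fps),
            class = "pose_sequence")
}

#' Number of frames in a pose sequence
#' @param seq A `pose_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  dim(seq$quats)[1L]
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("Pose sequence: %d frames x 24 joints @ %g fps\n",
              n_frames(x), x$fps))
  invisible(x)
}

# internal layout (4, 24, T) used by the batched kernels
.seq_internal <- function(seq) aperm(seq$quats, c(3L, 2L, 1L))

.seq_from_internal <- function(Q, beta, fps) {
  pose_sequence(aperm(Q, c(3L, 2L, 1L)), beta = beta, fps = fps)
}

#' Extract a pose chunk
#'
#' A chunk is a window of `n_window` (odd) consecutive frames centered on the
#' target frame; it is the unit of refinement.
#'
#' @param seq A `pose_sequence`.
#' @param center Index of the target (center) frame.
#' @param n_window Odd window length (default 17).
#' @return A `pose_chunk`: list with `quats` (`n_window x 24 x 4`), `beta`,
#'   `center_index` (position of the target inside the window,
#'   `(n_window + 1) / 2`).
#' @export
pose_chunk <- function(seq, center, n_window = 17L) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (n_window %% 2L != 1L) stop("n_window must be odd", call. = FALSE)
  half <- (n_window - 1L) %/% 2L
  t0 <- center - half; t1 <- center + half
  if (t0 < 1L || t1 > n_frames(seq)) {
    stop("chunk window extends beyond the sequence", call. = FALSE)
  }
  structure(list(quats = seq$quats[t0:t1, , , drop = FALSE],
                 beta = seq$beta,
                 center_index = half + 1L),
            class = "pose_chunk")
}

# chunk quats in internal (4, 24, N) layout
.chunk_internal <- function(chunk) aperm(chunk$quats, c(3L, 2L, 1L))

#' Convert a pose sequence to a 72-column axis-angle matrix
#'
#' Row `t` holds the 24 joint rotations of frame `t` in axis-angle form,
#' joint-major (joint 1 in columns 1:3, ...), matching the layout of SMPL
#' pose-parameter dumps.
#'
#' @param seq A `pose_sequence`.
#' @return A `T x 72` numeric matrix.
#' @export
pose_to_axis_angle_matrix <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  T_ <- n_frames(seq)
  out <- matrix(0, T_, 72L)
  for (j in 1:24) {
    aa <- quat_to_axis_angle(matrix(seq$quats[, j, ], ncol = 4L))
    out[, (3L * j - 2L):(3L * j)] <- aa
  }
  out
}

#' Build a pose sequence from a 72-column axis-angle matrix
#'
#' Inverse of [pose_to_axis_angle_matrix()].
#'
#' @param m A `T x 72` matrix of axis-angle pose parameters (joint-major).
#' @param beta Length-10 identity vector.
#' @param fps Frames per second.
#' @return A `pose_sequence`.
#' @export
axis_angle_matrix_to_pose <- function(m, beta = rep(0, 10), fps = 30) {
  m <- as.matrix(m)
  if (ncol(m) != 72L) stop("expected 72 columns (24 joints x 3)", call. = FALSE)
  T_ <- nrow(m)
  quats <- array(0, c(T_, 24L, 4L))
  for (j in 1:24) {
    quats[, j, ] <- axis_angle_to_quat(m[, (3L * j - 2L):(3L * j), drop = FALSE])
  }
  pose_sequence(quats, beta = beta, fps = fps)
}
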