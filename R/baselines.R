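# Non-learned baseline refiner: SLERP neighbor-midpoint smoothing.  The
# learned baselines (joint-wise Gaussian kernels, direct regression) are
# variants of refiner_params() and share refine_chunk()/refine_sequence().

# slerp path between one pair of unit quaternions at a vector of parameters
.slerp_pair_path <- function(q1, q2, tv) {
  d <- sum(q1 * q2)
  if (d < 0) { q2 <- -q2; d <- -d }
  if (d > 1 - 1e-10) {
    L <- outer(1 - tv, q1) + outer(tv, q2)
    return(L / sqrt(rowSums(L * L)))
  }
  om <- acos(min(1, d))
  (outer(sin((1 - tv) * om), q1) + outer(sin(tv * om), q2)) / sin(om)
}

# row-wise slerp for n x 4 matrices (same semantics as quat_slerp)
.slerp_rows <- function(A, B, t) {
  d <- rowSums(A * B)
  flip <- d < 0
  B[flip, ] <- -B[flip, , drop = FALSE]
  d <- abs(d)
  out <- matrix(0, nrow(A), 4L)
  near <- d > 1 - 1e-10
  if (any(near)) {
    L <- (1 - t) * A[near, , drop = FALSE] + t * B[near, , drop = FALSE]
    out[near, ] <- L / sqrt(rowSums(L * L))
  }
  if (any(!near)) {
    om <- acos(pmin(1, d[!near]))
    out[!near, ] <- (sin((1 - t) * om) * A[!near, , drop = FALSE] +
                       sin(t * om) * B[!near, , drop = FALSE]) / sin(om)
  }
  out
}

#' SLERP smoothing of a pose sequence
#'
#' Replaces each interior frame's joint rotations by the spherical
#' interpolation between its two (original) neighbors,
#' `slerp(q[t-1], q[t+1], t)`, endpoint frames copied through.  With `t = 0.5`
#' this is the neighbor-midpoint filter: exact on uniform geodesic motion,
#' noise-halving on independent jitter.  Multiple passes re-apply the filter
#' to its own output.
#'
#' @param seq A `pose_sequence` with at least 3 frames.
#' @param t Interpolation parameter (default 0.5, the midpoint).
#' @param passes Number of smoothing passes (default 1).
#' @return The smoothed `pose_sequence`.
#' @export
slerp_refine <- function(seq, t = 0.5, passes = 1L) {
  stopifnot(inherits(seq, "pose_sequence"))
  T_ <- n_frames(seq)
  if (T_ < 3L) {
    stop(errorCondition("SLERP smoothing needs at least 3 frames",
                        class = c("sequence_too_short", "error", "condition")))
  }
  quats <- seq$quats
  for (p in seq_len(passes)) {
    new <- quats
    for (j in 1:24) {
      A <- matrix(quats[1:(T_ - 2L), j, ], ncol = 4L)
      B <- matrix(quats[3:T_, j, ], ncol = 4L)
      new[2:(T_ - 1L), j, ] <- .slerp_rows(A, B, t)
    }
    quats <- new
  }
  pose_sequence(quats, beta = seq$beta, fps = seq$fps)
}

#' Refine a chunk with the learned Gaussian-kernel baseline
#'
#' The trunk regresses one standard deviation per joint; each joint's window
#' weights are a discrete Gaussian (evaluated at integer offsets from the
#' center, normalized to sum 1) and the joint's rotations are averaged with
#' its own kernel -- unlike the attention variant, weights differ across
#' joints.  As `sigma -> 0` the kernel tends to a one-hot on the center frame;
#' as `sigma -> Inf` it tends to the uniform mean.
#'
#' @param chunk A [pose_chunk()].
#' @param params A `"gaussian"`-variant [refiner_params()].
#' @return A 24 x 4 matrix of refined unit quaternions.
#' @export
gaussian_refine_chunk <- function(chunk, params) {
  stopifnot(inherits(params, "refiner_params"))
  if (params$variant != "gaussian") stop("params must be the gaussian variant", call. = FALSE)
  refine_chunk(chunk, params)
}

#' Refine a chunk with the direct-regression baseline
#'
#' The trunk's dense head outputs 96 values, reshaped to 24 quaternion blocks
#' and normalized per joint; no averaging of the input rotations occurs.
#'
#' @param chunk A [pose_chunk()].
#' @param params A `"direct"`-variant [refiner_params()].
#' @return A 24 x 4 matrix of refined unit quaternions.
#' @export
direct_regress_chunk <- function(chunk, params) {
  stopifnot(inherits(params, "refiner_params"))
  if (params$variant != "direct") stop("params must be the direct variant", call. = FALSE)
  refine_chunk(chunk, params)
}

#' Joint-wise Gaussian window weights for given standard deviations
#'
#' Helper exposing the kernel construction of the Gaussian baseline: discrete
#' Gaussian evaluated at integer offsets from the window center, normalized to
#' sum 1 per joint.
#'
#' @param std Vector of positive standard deviations (frames).
#' @param n_window Odd window length.
#' @return A `n_window x length(std)` matrix of simplex weights.
#' @export
gaussian_window_weights <- function(std, n_window) {
  stopifnot(all(std > 0), n_window %% 2L == 1L)
  ctr <- (n_window - 1L) %/% 2L + 1L
  d2 <- (seq_len(n_window) - ctr)^2
  K <- exp(outer(-d2 / 2, 1 / std^2))
  sweep(K, 2L, colSums(K), "/")
}
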