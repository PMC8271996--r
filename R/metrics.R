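# Training losses and evaluation metrics for refined-vs-ground-truth
# sequence pairs: L1 joint/mesh losses, squared-chordal pose loss, and the
# standard pose-estimation metrics MPJPE, PA-MPJPE, MPVE and acceleration
# error (all in mm; acceleration per frame^2, or per s^2 when fps is given).

.as_joint_array <- function(x, what) {
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3L] != 3L) {
    stop(what, " must be a (frames x joints x 3) array or a (joints x 3) matrix",
         call. = FALSE)
  }
  x
}

.check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch between inputs", call. = FALSE)
}

#' L1 joint loss
#'
#' Mean over joints of the L1 (sum of absolute coordinate differences) norm:
#' `(1/J) sum_j |x_hat_j - x_j|_1` with `J = 14` for the evaluation joint set.
#'
#' @param pred,gt J x 3 joint coordinate matrices (mm).
#' @return Nonnegative scalar (mm).
#' @export
loss_joint <- function(pred, gt) {
  pred <- as.matrix(pred); gt <- as.matrix(gt)
  .check_same_shape(pred, gt)
  sum(abs(pred - gt)) / nrow(pred)
}

#' L1 mesh loss
#'
#' Mean over vertices of the L1 coordinate difference.
#'
#' @param pred,gt V x 3 vertex coordinate matrices (mm).
#' @return Nonnegative scalar (mm).
#' @export
loss_mesh <- function(pred, gt) {
  pred <- as.matrix(pred); gt <- as.matrix(gt)
  .check_same_shape(pred, gt)
  sum(abs(pred - gt)) / nrow(pred)
}

#' Squared-chordal pose loss
#'
#' Mean over the 24 joints of the squared Frobenius distance between
#' estimated and ground-truth rotation matrices.
#'
#' @param pred,gt 3 x 3 x 24 arrays of rotation matrices.
#' @return Nonnegative scalar.
#' @export
loss_pose <- function(pred, gt) {
  stopifnot(is.array(pred), is.array(gt),
            identical(dim(pred), c(3L, 3L, 24L)), identical(dim(gt), dim(pred)))
  total <- 0
  for (j in 1:24) total <- total + chordal_sq_distance(pred[, , j], gt[, , j])
  total / 24
}

#' Weighted total loss
#'
#' `lambda_joint * L_joint + lambda_mesh * L_mesh + lambda_pose * L_pose`.
#' The package default `(1, 0, 0)` supervises the regressed joints only.
#'
#' @param losses Named list or vector with elements `joint`, `mesh`, `pose`.
#' @param weights Length-3 nonnegative weights `(joint, mesh, pose)`.
#' @return Scalar.
#' @export
total_loss <- function(losses, weights = c(1, 0, 0)) {
  if (any(weights < 0)) stop("loss weights must be nonnegative", call. = FALSE)
  l <- unlist(losses)[c("joint", "mesh", "pose")]
  l[is.na(l)] <- 0
  sum(weights * l)
}

#' Mean per-joint position error (MPJPE)
#'
#' Euclidean joint distance in mm, averaged over frames and joints, after
#' optional per-frame root-joint translation alignment.  Kinematic outputs of
#' this package are already pelvis-centered, so `root_index = NULL` is the
#' default.
#'
#' @param pred,gt `(T x J x 3)` joint arrays (a single `J x 3` frame is
#'   accepted).
#' @param root_index Joint used for per-frame translation alignment, or `NULL`
#'   for none.
#' @return MPJPE in mm.
#' @export
mpjpe <- function(pred, gt, root_index = NULL) {
  pred <- .as_joint_array(pred, "pred"); gt <- .as_joint_array(gt, "gt")
  .check_same_shape(pred, gt)
  if (!is.null(root_index)) {
    pred <- sweep(pred, c(1L, 3L), pred[, root_index, ])
    gt <- sweep(gt, c(1L, 3L), gt[, root_index, ])
  }
  mean(sqrt(apply((pred - gt)^2, c(1L, 2L), sum)))
}

#' Mean per-vertex position error (MPVE)
#'
#' Identical to [mpjpe()] but over mesh vertices.
#'
#' @inheritParams mpjpe
#' @return MPVE in mm.
#' @export
mpve <- function(pred, gt, root_index = NULL) mpjpe(pred, gt, root_index)

# similarity (rotation + translation + uniform scale) Procrustes of X onto Y,
# both J x 3 row-coordinate matrices.  Rotation from the SVD of the
# cross-covariance with the usual determinant correction; for degenerate
# (rank-deficient) configurations LAPACK's deterministic singular-vector
# choice fixes the tie.
.procrustes_similarity <- function(X, Y) {
  mux <- colMeans(X); muy <- colMeans(Y)
  Xc <- sweep(X, 2L, mux); Yc <- sweep(Y, 2L, muy)
  C <- t(Xc) %*% Yc
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  denom <- sum(Xc * Xc)
  s <- if (denom > 0) sum(sv$d * c(1, 1, d)) / denom else 1
  sweep(s * Xc %*% R, 2L, muy, "+")
}

#' Procrustes-aligned MPJPE (PA-MPJPE)
#'
#' Per frame, the prediction is aligned onto the ground truth by the
#' least-squares similarity transform (rotation, translation and uniform
#' scale), then the mean joint distance is taken; frame means are averaged.
#'
#' @inheritParams mpjpe
#' @return PA-MPJPE in mm.
#' @export
pa_mpjpe <- function(pred, gt) {
  pred <- .as_joint_array(pred, "pred"); gt <- .as_joint_array(gt, "gt")
  .check_same_shape(pred, gt)
  T_ <- dim(pred)[1L]
  per_frame <- vapply(seq_len(T_), function(t) {
    A <- .procrustes_similarity(matrix(pred[t, , ], ncol = 3L),
                                matrix(gt[t, , ], ncol = 3L))
    mean(sqrt(rowSums((A - matrix(gt[t, , ], ncol = 3L))^2)))
  }, 0)
  mean(per_frame)
}

# second differences along frames of a (T x J x 3) array -> (T-2 x J x 3)
.second_diff <- function(x) {
  T_ <- dim(x)[1L]
  x[3:T_, , , drop = FALSE] - 2 * x[2:(T_ - 1L), , , drop = FALSE] +
    x[1:(T_ - 2L), , , drop = FALSE]
}

#' Acceleration error
#'
#' Per-joint acceleration at frame `t` is the second finite difference
#' `x[t+1] - 2 x[t] + x[t-1]`; the error is the mean (over interior frames
#' and joints) Euclidean norm of the difference between predicted and
#' ground-truth accelerations, in mm/frame^2, multiplied by `fps^2` (giving
#' mm/s^2) when a frame rate is supplied.  Adding any trajectory that is
#' affine in time to both inputs leaves the result unchanged.
#'
#' @inheritParams mpjpe
#' @param fps Optional frame rate for mm/s^2 scaling.
#' @return Acceleration error.
#' @export
accel_error <- function(pred, gt, fps = NULL) {
  tr <- accel_error_trace(pred, gt, fps)
  mean(tr)
}

#' Per-frame acceleration-error trace
#'
#' The acceleration error of [accel_error()] before averaging over frames:
#' one value per interior frame (mean over joints), e.g. for plotting error
#' peaks along a video.
#'
#' @inheritParams accel_error
#' @return Numeric vector of length `T - 2`.
#' @export
accel_error_trace <- function(pred, gt, fps = NULL) {
  pred <- .as_joint_array(pred, "pred"); gt <- .as_joint_array(gt, "gt")
  .check_same_shape(pred, gt)
  if (dim(pred)[1L] < 3L) {
    stop(errorCondition("acceleration error needs at least 3 frames",
                        class = c("sequence_too_short", "error", "condition")))
  }
  d <- .second_diff(pred) - .second_diff(gt)
  tr <- rowMeans(sqrt(apply(d^2, c(1L, 2L), sum)))
  if (!is.null(fps)) tr <- tr * fps^2
  tr
}

#' Write a metric report
#'
#' Writes an evaluation table as tab-delimited text or structured JSON.
#'
#' @param report A data frame (e.g. from [evaluate_refinement()]).
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(report, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
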