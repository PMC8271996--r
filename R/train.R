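# Training loop and evaluation orchestration.  Training follows the study
# protocol: Adam at a fixed learning rate, randomly shuffled chunks each
# iteration, and the loss evaluated on the 14 regressed joints of the
# refined center frame only; gradients flow end-to-end through the quaternion
# normalization and forward kinematics (no gradient stopping).

#' Training configuration
#'
#' Defaults are the reference protocol: window 17, Adam at 1e-4 with no
#' decay, batch 64, 20 epochs of 1000 iterations, joint-only loss weights
#' `(1, 0, 0)`.
#'
#' @param n_window Odd chunk length.
#' @param learning_rate Adam learning rate (constant).
#' @param batch_size Chunks per iteration.
#' @param epochs Number of epochs.
#' @param iterations_per_epoch Iterations per epoch.
#' @param loss_weights Length-3 nonnegative weights `(joint, mesh, pose)`.
#' @param seed Integer seed controlling initialization and chunk sampling.
#' @param variant Refiner variant to train.
#' @param hidden Trunk channel widths.
#' @return A `train_config` list.
#' @export
train_config <- function(n_window = 17L, learning_rate = 1e-4, batch_size = 64L,
                         epochs = 20L, iterations_per_epoch = 1000L,
                         loss_weights = c(1, 0, 0), seed = 1L,
                         variant = c("attention", "gaussian", "direct"),
                         hidden = c(64L, 48L)) {
  variant <- match.arg(variant)
  stopifnot(n_window %% 2L == 1L, n_window >= 3L, learning_rate > 0,
            batch_size >= 1L, epochs >= 1L, iterations_per_epoch >= 1L,
            length(loss_weights) == 3L, all(loss_weights >= 0))
  structure(list(n_window = as.integer(n_window), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 iterations_per_epoch = as.integer(iterations_per_epoch),
                 loss_weights = as.numeric(loss_weights), seed = as.integer(seed),
                 variant = variant, hidden = as.integer(hidden)),
            class = "train_config")
}

# batched linear blend skinning for the mesh loss; offs/jr per sample
.lbs_batch <- function(fwd, template, jr) {
  B <- dim(fwd$X)[3L]
  V <- template$n_vertices
  D <- t(template$vertex_template)
  W <- template$skinning_weights
  out <- array(0, c(3L, V, B))
  for (b in seq_len(B)) {
    Gcat <- matrix(0, 3L, 72L)
    Dstack <- matrix(0, 72L, V)
    for (j in 1:24) {
      rows <- (3L * j - 2L):(3L * j)
      Gcat[, rows] <- fwd$G[[j]][, , b]
      Dstack[rows, ] <- (D - jr[, j, b]) * rep(W[, j], each = 3L)
    }
    out[, , b] <- Gcat %*% Dstack + matrix(fwd$X[, , b], 3L) %*% t(W)
  }
  out
}

# gradients of .lbs_batch: dV (3, V, B) -> list(dG per joint, dX (3, 24, B))
.lbs_batch_backward <- function(fwd, template, jr, dV) {
  B <- dim(fwd$X)[3L]
  D <- t(template$vertex_template)
  W <- template$skinning_weights
  dG <- rep(list(array(0, c(3L, 3L, B))), 24L)
  dX <- array(0, c(3L, 24L, B))
  for (b in seq_len(B)) {
    dVb <- matrix(dV[, , b], 3L)
    dX[, , b] <- dVb %*% W
    for (j in 1:24) {
      dVw <- dVb * rep(W[, j], each = 3L)
      dG[[j]][, , b] <- dVw %*% t(D - jr[, j, b])
    }
  }
  list(dG = dG, dX = dX)
}

# cumulative (rest) joint positions per sample from batched offsets
.rest_joints_batch <- function(offs, parents) {
  jr <- array(0, dim(offs))
  jr[, 1L, ] <- offs[, 1L, ]
  for (j in 2:24) {
    jr[, j, ] <- matrix(jr[, parents[j], ], 3L) + matrix(offs[, j, ], 3L)
  }
  jr
}

# forward + backward of the supervised loss head on a batch of refined
# center poses Y (4,24,B) against ground-truth poses gtQ, both run through
# the body model with per-sample offsets offs (3,24,B).
.training_loss <- function(Y, gtQ, offs, template, lw) {
  B <- dim(Y)[3L]
  parents <- template$parent_index
  fwdP <- .fk_batch(Y, offs, parents)
  fwdG <- .fk_batch(gtQ, offs, parents)
  reg <- template$joint_regressor_14
  X24p <- matrix(aperm(fwdP$X, c(2L, 1L, 3L)), 24L)
  X24g <- matrix(aperm(fwdG$X, c(2L, 1L, 3L)), 24L)
  diff <- reg %*% X24p - reg %*% X24g
  l_joint <- sum(abs(diff)) / (14 * B)
  dX14 <- sign(diff) * (lw[1L] / (14 * B))
  dX24 <- aperm(array(t(reg) %*% dX14, c(24L, 3L, B)), c(2L, 1L, 3L))
  l_mesh <- 0; l_pose <- 0
  dG_extra <- NULL
  if (lw[2L] > 0) {
    jr <- .rest_joints_batch(offs, parents)
    Vp <- .lbs_batch(fwdP, template, jr)
    Vg <- .lbs_batch(fwdG, template, jr)
    V <- template$n_vertices
    dmesh <- Vp - Vg
    l_mesh <- sum(abs(dmesh)) / (V * B)
    lb <- .lbs_batch_backward(fwdP, template, jr, sign(dmesh) * (lw[2L] / (V * B)))
    dG_extra <- lb$dG
    dX24 <- dX24 + lb$dX
  }
  dQ_extra <- NULL
  if (lw[3L] > 0) {
    dQ_extra <- array(0, c(4L, 24L, B))
    for (j in 1:24) {
      dRj <- fwdP$R[[j]] - fwdG$R[[j]]
      l_pose <- l_pose + sum(dRj * dRj)
      dQ_extra[, j, ] <- .dmat_dquat(matrix(Y[, j, ], 4L),
                                     dRj * (2 * lw[3L] / (24 * B)))
    }
    l_pose <- l_pose / (24 * B)
  }
  dY <- .fk_batch_backward(fwdP, dX24, dG_extra)
  if (!is.null(dQ_extra)) dY <- dY + dQ_extra
  loss <- lw[1L] * l_joint + lw[2L] * l_mesh + lw[3L] * l_pose
  list(loss = loss, dY = dY,
       components = c(joint = l_joint, mesh = l_mesh, pose = l_pose))
}

.grads_flatten <- function(gr) {
  out <- list()
  for (l in seq_along(gr)) {
    nm <- paste0("layer", l)
    for (k in names(gr[[nm]])) out[[paste0(nm, ".", k)]] <- gr[[nm]][[k]]
  }
  out
}

#' Train a refiner on a synthetic corpus
#'
#' Each iteration samples `batch_size` chunks uniformly over (sequence,
#' valid center frame) pairs, refines their center poses, runs the body model
#' on refined and ground-truth center poses, and applies the weighted loss to
#' the 14 regressed joints (plus optional mesh and pose terms).  Adam updates
#' at a constant learning rate.  The whole run is a pure function of the
#' corpus and `config$seed`; a non-finite loss raises a `training_failure`
#' error carrying the partial trace.
#'
#' @param corpus A [make_training_corpus()] result.
#' @param config A [train_config()].
#' @return A `refiner_fit`: list with `params`, `config`, `loss_trace`.
#' @export
train_refiner <- function(corpus, config) {
  stopifnot(inherits(corpus, "pose_corpus"), inherits(config, "train_config"))
  template <- corpus$template
  N <- config$n_window
  half <- (N - 1L) %/% 2L
  if (corpus$n_frames < N) stop("corpus sequences shorter than the chunk window", call. = FALSE)
  lw <- config$loss_weights
  .with_seed(config$seed, {
    params <- refiner_params(config$variant, N, config$hidden, seed = NULL)
    flat <- .params_flatten(params)
    state <- .adam_init(flat)
    noisy_int <- lapply(corpus$pairs, function(p) .seq_internal(p$noisy))
    gt_int <- lapply(corpus$pairs, function(p) .seq_internal(p$gt))
    offs_seq <- lapply(corpus$pairs,
                       function(p) t(shape_skeleton(template, p$noisy$beta)))
    n_iter <- config$epochs * config$iterations_per_epoch
    trace <- numeric(n_iter)
    Bz <- config$batch_size
    for (it in seq_len(n_iter)) {
      batch <- corpus$sample_batch(Bz, N)
      Q <- array(0, c(4L, 24L, N, Bz))
      gtQ <- array(0, c(4L, 24L, Bz))
      offs <- array(0, c(3L, 24L, Bz))
      for (b in seq_len(Bz)) {
        s <- batch$sequence[b]; cf <- batch$center[b]
        Q[, , , b] <- noisy_int[[s]][, , (cf - half):(cf + half)]
        gtQ[, , b] <- gt_int[[s]][, , cf]
        offs[, , b] <- offs_seq[[s]]
      }
      fw <- .variant_forward(Q, params)
      lh <- .training_loss(fw$Y, gtQ, offs, template, lw)
      trace[it] <- lh$loss
      if (!is.finite(lh$loss)) {
        stop(errorCondition("training diverged: non-finite loss",
                            trace = trace[seq_len(it)],
                            class = c("training_failure", "error", "condition")))
      }
      gr <- .variant_backward(fw, lh$dY, params)
      upd <- .adam_step(flat, .grads_flatten(gr), state,
                        config$learning_rate, t = it)
      flat <- upd$params
      state <- upd$state
      params <- .params_unflatten(params, flat)
    }
    structure(list(params = params, config = config, loss_trace = trace),
              class = "refiner_fit")
  })
}

#' @export
print.refiner_fit <- function(x, ...) {
  cat(sprintf("Trained %s refiner: %d iterations, final loss %.3f (first %.3f)\n",
              x$config$variant, length(x$loss_trace),
              utils::tail(x$loss_trace, 1L), x$loss_trace[1L]))
  invisible(x)
}

.as_params <- function(x) {
  if (inherits(x, "refiner_fit")) x$params
  else if (inherits(x, "refiner_params")) x
  else stop("expected a refiner_fit or refiner_params object", call. = FALSE)
}

# 14-joint trajectories (T x 14 x 3) of a sequence through the body model
.sequence_joints14 <- function(seq, template) {
  T_ <- n_frames(seq)
  offs <- array(t(shape_skeleton(template, seq$beta)), c(3L, 24L, T_))
  fwd <- .fk_batch(.seq_internal(seq), offs, template$parent_index)
  X14 <- template$joint_regressor_14 %*% matrix(aperm(fwd$X, c(2L, 1L, 3L)), 24L)
  aperm(array(X14, c(14L, 3L, T_)), c(3L, 1L, 2L))
}

# posed vertices (T x V x 3) of a sequence
.sequence_vertices <- function(seq, template) {
  T_ <- n_frames(seq)
  offs3 <- t(shape_skeleton(template, seq$beta))
  fwd <- .fk_batch(.seq_internal(seq), array(offs3, c(3L, 24L, T_)),
                   template$parent_index)
  jr <- .cumulative_offsets(t(offs3))
  D <- t(template$vertex_template)
  W <- template$skinning_weights
  V <- template$n_vertices
  Dstack <- matrix(0, 72L, V)
  for (j in 1:24) {
    Dstack[(3L * j - 2L):(3L * j), ] <- (D - jr[j, ]) * rep(W[, j], each = 3L)
  }
  out <- array(0, c(T_, V, 3L))
  Gcat <- matrix(0, 3L, 72L)
  for (t in seq_len(T_)) {
    for (j in 1:24) Gcat[, (3L * j - 2L):(3L * j)] <- fwd$G[[j]][, , t]
    out[t, , ] <- t(Gcat %*% Dstack + matrix(fwd$X[, , t], 3L) %*% t(W))
  }
  out
}

#' Evaluate refinement against ground truth
#'
#' Refines each noisy test sequence with the given parameters, computes
#' MPJPE, PA-MPJPE, MPVE and acceleration error for both the refined and the
#' raw noisy sequence against ground truth, and averages over sequences.
#' The `floor(n_window / 2)` frames at each end are excluded from all metric
#' computations, mirroring the refinement boundary rule.
#'
#' @param fit A `refiner_fit` or `refiner_params` object.
#' @param pairs List of `list(noisy, gt)` sequence pairs (e.g.
#'   `corpus$pairs`).
#' @param template A `body_template`.
#' @param exclude Frames dropped at each end (default `floor(n_window / 2)`).
#' @param fps Optional frame rate for mm/s^2 acceleration units (default:
#'   per-frame^2 units).
#' @param include_mpve Compute the vertex metric (slower); default `TRUE`.
#' @return A data frame with rows `refined` and `noisy`; per-sequence values
#'   in `attr(, "per_sequence")`.
#' @export
evaluate_refinement <- function(fit, pairs, template,
                                exclude = NULL, fps = NULL, include_mpve = TRUE) {
  params <- .as_params(fit)
  if (is.null(exclude)) exclude <- (params$n_window - 1L) %/% 2L
  refined <- lapply(pairs, function(p) refine_sequence(p$noisy, params))
  methods <- list(refined = refined,
                  noisy = lapply(pairs, function(p) p$noisy))
  .evaluate_methods(methods, pairs, template, exclude, fps, include_mpve)
}

# shared evaluation over named lists of refined sequences
.evaluate_methods <- function(methods, pairs, template, exclude, fps,
                              include_mpve) {
  per_seq <- list()
  gtJ <- lapply(pairs, function(p) .sequence_joints14(p$gt, template))
  gtV <- if (include_mpve) {
    lapply(pairs, function(p) .sequence_vertices(p$gt, template))
  }
  rows <- lapply(names(methods), function(m) {
    vals <- vapply(seq_along(pairs), function(i) {
      s <- methods[[m]][[i]]
      T_ <- n_frames(s)
      keep <- (exclude + 1L):(T_ - exclude)
      J <- .sequence_joints14(s, template)[keep, , , drop = FALSE]
      G <- gtJ[[i]][keep, , , drop = FALSE]
      mv <- if (include_mpve) {
        mpve(.sequence_vertices(s, template)[keep, , , drop = FALSE],
             gtV[[i]][keep, , , drop = FALSE])
      } else NA_real_
      c(mpjpe(J, G), pa_mpjpe(J, G), mv, accel_error(J, G, fps))
    }, numeric(4L))
    per_seq[[m]] <<- t(vals)
    data.frame(method = m, mpjpe = mean(vals[1L, ]), pa_mpjpe = mean(vals[2L, ]),
               mpve = mean(vals[3L, ]), accel_error = mean(vals[4L, ]))
  })
  out <- do.call(rbind, rows)
  attr(out, "per_sequence") <- per_seq
  out
}

#' Compare refiners on a shared benchmark
#'
#' Trains the attention, Gaussian-kernel and direct-regression refiners with
#' identical budgets on the same corpus, evaluates them on the test pairs
#' together with SLERP smoothing and the raw noisy input, and returns one row
#' per method.
#'
#' @param corpus Training corpus ([make_training_corpus()]).
#' @param test_pairs Held-out `list(noisy, gt)` pairs.
#' @param config A [train_config()]; its `variant` field is overridden.
#' @param variants Learned variants to include.
#' @param include_slerp Add the SLERP smoothing row.
#' @param ... Passed to [evaluate_refinement()] internals (`fps`,
#'   `include_mpve`).
#' @inheritParams evaluate_refinement
#' @return Data frame with one row per method plus the noisy baseline.
#' @export
compare_refiners <- function(corpus, test_pairs, config, template = corpus$template,
                             variants = c("attention", "gaussian", "direct"),
                             include_slerp = TRUE, exclude = NULL, fps = NULL,
                             include_mpve = TRUE) {
  if (is.null(exclude)) exclude <- (config$n_window - 1L) %/% 2L
  methods <- list()
  for (v in variants) {
    cfg <- config
    cfg$variant <- v
    fit <- train_refiner(corpus, cfg)
    methods[[v]] <- lapply(test_pairs, function(p) refine_sequence(p$noisy, fit$params))
  }
  if (include_slerp) {
    methods$slerp <- lapply(test_pairs, function(p) slerp_refine(p$noisy))
  }
  methods$noisy <- lapply(test_pairs, function(p) p$noisy)
  .evaluate_methods(methods, test_pairs, template, exclude, fps, include_mpve)
}
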