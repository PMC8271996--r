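# The refiner core: positional encoding, temporal-convolution feature
# extractor, non-local affinity weights, and per-joint weighted quaternion
# averaging, applied to sliding windows of a pose sequence.
#
# Three variants share the two-layer convolutional trunk:
#   * "attention": third conv layer (kernel 3) -> 24 x N features -> affinity
#     weights softmax(H^T h_center), one shared weight vector per chunk;
#   * "gaussian": dense head regressing 24 joint-wise standard deviations,
#     turned into per-joint discrete Gaussian kernels centered on the window;
#   * "direct": dense head regressing the 96-D center pose directly,
#     normalized per joint.

#' Initialize refiner parameters
#'
#' Creates the weight-regression network for one of the three refiner
#' variants.  All variants use two 1-D convolution layers (kernel 3, zero
#' padding, channel widths `97 -> hidden[1] -> hidden[2]`), each followed by
#' layer normalization over channels and ReLU.  The `"attention"` variant adds
#' a third such layer down to 24 channels; `"gaussian"` and `"direct"` replace
#' it with a dense layer over the whole window (kernel width `n_window`) with
#' 24 and 96 output channels respectively.
#'
#' @param variant One of `"attention"`, `"gaussian"`, `"direct"`.
#' @param n_window Odd window length (default 17).
#' @param hidden Channel widths of the two trunk layers (default `c(64, 48)`).
#' @param seed Integer seed for Glorot-uniform initialization, or `NULL` to
#'   draw from the caller's RNG stream.
#' @return A `refiner_params` object (list of layers plus configuration).
#' @export
refiner_params <- function(variant = c("attention", "gaussian", "direct"),
                           n_window = 17L, hidden = c(64L, 48L), seed = 1L) {
  variant <- match.arg(variant)
  if (n_window %% 2L != 1L || n_window < 3L) stop("n_window must be odd and >= 3", call. = FALSE)
  build <- function() {
    mk_conv <- function(nout, nin) list(W = .glorot(nout, nin, 3L),
                                        b = numeric(nout),
                                        g = rep(1, nout), be = numeric(nout))
    layers <- list(mk_conv(hidden[1L], 97L), mk_conv(hidden[2L], hidden[1L]))
    layers[[3L]] <- switch(variant,
      attention = mk_conv(24L, hidden[2L]),
      gaussian = list(W = .glorot(24L, hidden[2L] * n_window), b = numeric(24L)),
      direct = list(W = .glorot(96L, hidden[2L] * n_window), b = numeric(96L)))
    structure(list(variant = variant, n_window = as.integer(n_window),
                   hidden = as.integer(hidden), layers = layers),
              class = c(paste0(variant, "_refiner"), "refiner_params"))
  }
  if (is.null(seed)) build() else .with_seed(seed, build())
}

#' @export
print.refiner_params <- function(x, ...) {
  np <- sum(vapply(.params_flatten(x), length, 1L))
  cat(sprintf("Refiner parameters: variant '%s', window %d, trunk %s, %d parameters\n",
              x$variant, x$n_window, paste(x$hidden, collapse = "-"), np))
  invisible(x)
}

#' Positional encoding of a pose chunk
#'
#' Stacks the 24 joint quaternions joint-major (joint 1 in rows 1-4, ...) into
#' a 96 x N matrix and appends the relative position index row
#' `-floor(N/2), ..., 0, ..., floor(N/2)` as row 97.
#'
#' @param chunk A [pose_chunk()].
#' @return A 97 x N numeric matrix.
#' @export
encode_positions <- function(chunk) {
  stopifnot(inherits(chunk, "pose_chunk"))
  N <- dim(chunk$quats)[1L]
  if (N %% 2L != 1L) stop("chunk length must be odd", call. = FALSE)
  Q <- .chunk_internal(chunk)                  # (4, 24, N)
  half <- (N - 1L) %/% 2L
  rbind(matrix(Q, 96L, N), seq(-half, half))
}

#' Temporal features from an encoded chunk
#'
#' Runs the encoded chunk through the convolutional trunk (all three layers
#' for the attention variant): per layer conv(kernel 3, zero padding), layer
#' normalization over channels, ReLU.
#'
#' @param enc A 97 x N encoded chunk from [encode_positions()].
#' @param params An `"attention"`-variant [refiner_params()].
#' @return The 24 x N temporal feature matrix H.
#' @export
extract_features <- function(enc, params) {
  stopifnot(inherits(params, "refiner_params"))
  if (params$variant != "attention") {
    stop("extract_features() expects the attention variant", call. = FALSE)
  }
  if (!is.matrix(enc) || nrow(enc) != 97L) stop("encoded chunk must be 97 x N", call. = FALSE)
  X <- array(enc, c(97L, ncol(enc), 1L))
  for (l in 1:3) X <- array(.conv_block_forward(X, params$layers[[l]])$A,
                            c(dim(params$layers[[l]]$W)[1L], ncol(enc), 1L))
  matrix(X, 24L, ncol(enc))
}

#' Affinity weights from temporal features
#'
#' The non-local self-attention step: `w = softmax(H^T h_center)` with no
#' scaling factor and no learned projections; `h_center` is the feature column
#' of the window's center frame.
#'
#' @param H A 24 x N temporal feature matrix.
#' @return Length-N positive weights summing to 1.
#' @export
compute_affinity <- function(H) {
  stopifnot(is.matrix(H))
  N <- ncol(H)
  hc <- H[, (N - 1L) %/% 2L + 1L]
  drop(.softmax_cols(matrix(t(H) %*% hc, ncol = 1L)))
}

# ---- shared internal forward/backward over a batch of chunks --------------

# weighted quaternion mean over the window, batched over (joint, sample)
# columns.  Q (4, 24, N, B); Wfull (N, 24*B) per-column simplex weights.
.wmean_forward <- function(Q, Wfull) {
  d <- dim(Q); N <- d[3L]; B <- d[4L]
  ctr <- (N - 1L) %/% 2L + 1L
  ref <- .m4(Q[, , ctr, ], 24L * B)
  S <- matrix(0, 4L, 24L * B)
  sgn <- matrix(0, N, 24L * B)
  for (n in seq_len(N)) {
    Qn <- .m4(Q[, , n, ], 24L * B)
    sg <- 1 - 2 * (colSums(Qn * ref) < 0)
    sgn[n, ] <- sg
    S <- S + Qn * rep(sg * Wfull[n, ], each = 4L)
  }
  nrm <- sqrt(colSums(S * S))
  if (any(nrm < 1e-8)) {
    stop(errorCondition("degenerate quaternion average: near-antipodal cancellation in a window",
                        class = c("degenerate_average", "error", "condition")))
  }
  Y <- S / rep(nrm, each = 4L)
  list(Y = Y, S = S, nrm = nrm, sgn = sgn)
}

# dY (4, 24B) -> gradient w.r.t. the per-column weights (N, 24B)
.wmean_backward <- function(cache, Q, dY) {
  d <- dim(Q); N <- d[3L]
  proj <- colSums(cache$Y * dY)
  dS <- (dY - cache$Y * rep(proj, each = 4L)) / rep(cache$nrm, each = 4L)
  nc <- ncol(dY)
  dW <- matrix(0, N, nc)
  for (n in seq_len(N)) {
    dW[n, ] <- colSums(.m4(Q[, , n, ], nc) * dS) * cache$sgn[n, ]
  }
  dW
}

.trunk_forward <- function(Q, params) {
  d <- dim(Q); N <- d[3L]; B <- d[4L]
  half <- (N - 1L) %/% 2L
  X <- array(0, c(97L, N, B))
  X[1:96, , ] <- array(Q, c(96L, N, B))
  X[97L, , ] <- seq(-half, half)
  c1 <- .conv_block_forward(X, params$layers[[1L]])
  A1 <- array(c1$A, c(params$hidden[1L], N, B))
  c2 <- .conv_block_forward(A1, params$layers[[2L]])
  A2 <- array(c2$A, c(params$hidden[2L], N, B))
  list(c1 = c1, c2 = c2, A2 = A2, N = N, B = B)
}

.trunk_backward <- function(tr, dA2, params) {
  b2 <- .conv_block_backward(tr$c2, matrix(dA2, params$hidden[2L]),
                             params$layers[[2L]], need_input_grad = TRUE)
  b1 <- .conv_block_backward(tr$c1, matrix(b2$dX, params$hidden[1L]),
                             params$layers[[1L]], need_input_grad = FALSE)
  list(layer1 = b1$grads, layer2 = b2$grads)
}

# attention variant: full forward over a batch of chunks Q (4, 24, N, B)
.attention_forward <- function(Q, params) {
  tr <- .trunk_forward(Q, params)
  N <- tr$N; B <- tr$B
  c3 <- .conv_block_forward(tr$A2, params$layers[[3L]])
  H <- array(c3$A, c(24L, N, B))
  ctr <- (N - 1L) %/% 2L + 1L
  Hc <- .mC(H[, ctr, ], 24L)                         # (24, B)
  Hm <- .mC(c3$A, 24L)                               # (24, N*B)
  logits <- matrix(colSums(Hm * Hc[, rep(seq_len(B), each = N)]), N, B)
  W <- .softmax_cols(logits)                         # (N, B)
  Wfull <- matrix(0, N, 24L * B)
  for (n in seq_len(N)) Wfull[n, ] <- rep(W[n, ], each = 24L)
  wm <- .wmean_forward(Q, Wfull)
  list(Y = array(wm$Y, c(4L, 24L, B)), weights = W,
       cache = list(tr = tr, c3 = c3, H = H, Hc = Hc, W = W, wm = wm, Q = Q))
}

.attention_backward <- function(fw, dY, params) {
  ca <- fw$cache
  N <- ca$tr$N; B <- ca$tr$B
  ctr <- (N - 1L) %/% 2L + 1L
  dWfull <- .wmean_backward(ca$wm, ca$Q, .mC(dY, 4L))
  dW <- matrix(0, N, B)
  dWa <- array(dWfull, c(N, 24L, B))
  for (j in 1:24) dW <- dW + .mC(dWa[, j, ], N)
  dlogits <- .softmax_cols_backward(ca$W, dW)
  # logits[n, b] = sum_ch H[ch, n, b] * Hc[ch, b]
  dH <- array(0, c(24L, N, B))
  dHc <- matrix(0, 24L, B)
  for (n in seq_len(N)) {
    dH[, n, ] <- ca$Hc * rep(dlogits[n, ], each = 24L)
    dHc <- dHc + .mC(ca$H[, n, ], 24L) * rep(dlogits[n, ], each = 24L)
  }
  dH[, ctr, ] <- .mC(dH[, ctr, ], 24L) + dHc
  b3 <- .conv_block_backward(ca$c3, matrix(dH, 24L), params$layers[[3L]],
                             need_input_grad = TRUE)
  gr <- .trunk_backward(ca$tr, b3$dX, params)
  gr$layer3 <- b3$grads
  gr
}

# gaussian variant: dense head -> softplus std devs -> per-joint kernels
.gaussian_forward <- function(Q, params) {
  tr <- .trunk_forward(Q, params)
  N <- tr$N; B <- tr$B
  Fm <- matrix(tr$A2, params$hidden[2L] * N, B)
  A <- params$layers[[3L]]$W %*% Fm + params$layers[[3L]]$b   # (24, B)
  sp <- ifelse(A > 30, A, log1p(exp(A)))
  sig <- sp + 1e-3
  ctr <- (N - 1L) %/% 2L + 1L
  d2 <- (seq_len(N) - ctr)^2
  sigf <- as.vector(sig)                                      # (24*B), joint-major
  K <- exp(outer(-d2 / 2, 1 / sigf^2))                        # (N, 24B)
  Wfull <- sweep(K, 2L, colSums(K), "/")
  wm <- .wmean_forward(Q, Wfull)
  list(Y = array(wm$Y, c(4L, 24L, B)), std = matrix(sig, 24L, B),
       cache = list(tr = tr, Fm = Fm, A = A, sigf = sigf, d2 = d2,
                    Wfull = Wfull, wm = wm, Q = Q))
}

.gaussian_backward <- function(fw, dY, params) {
  ca <- fw$cache
  N <- ca$tr$N; B <- ca$tr$B
  dWfull <- .wmean_backward(ca$wm, ca$Q, matrix(dY, 4L))
  # d(normalized kernel)/d sigma = w_n (d_n^2 - sum_m w_m d_m^2) / sigma^3
  wd2 <- colSums(ca$Wfull * ca$d2)
  dsig <- colSums(dWfull * ca$Wfull *
                    (ca$d2 - matrix(wd2, N, length(wd2), byrow = TRUE))) / ca$sigf^3
  dA <- matrix(dsig, 24L, B) * (1 / (1 + exp(-ca$A)))
  dWd <- dA %*% t(ca$Fm)
  db <- rowSums(dA)
  dFm <- t(params$layers[[3L]]$W) %*% dA
  gr <- .trunk_backward(ca$tr, array(dFm, c(params$hidden[2L], N, B)), params)
  gr$layer3 <- list(W = dWd, b = db)
  gr
}

# direct-regression variant: dense head -> 96 values -> per-joint normalize
.direct_forward <- function(Q, params) {
  tr <- .trunk_forward(Q, params)
  N <- tr$N; B <- tr$B
  Fm <- matrix(tr$A2, params$hidden[2L] * N, B)
  A <- params$layers[[3L]]$W %*% Fm + params$layers[[3L]]$b   # (96, B)
  Yr <- matrix(A, 4L)                                         # (4, 24B)
  nrm <- sqrt(colSums(Yr * Yr))
  if (any(nrm < 1e-8)) {
    stop(errorCondition("degenerate direct-regression output: near-zero quaternion block",
                        class = c("degenerate_output", "error", "condition")))
  }
  Y <- Yr / rep(nrm, each = 4L)
  list(Y = array(Y, c(4L, 24L, B)),
       cache = list(tr = tr, Fm = Fm, Yr = Yr, nrm = nrm, Y = Y))
}

.direct_backward <- function(fw, dY, params) {
  ca <- fw$cache
  N <- ca$tr$N; B <- ca$tr$B
  dYm <- matrix(dY, 4L)
  proj <- colSums(ca$Y * dYm)
  dYr <- (dYm - ca$Y * rep(proj, each = 4L)) / rep(ca$nrm, each = 4L)
  dA <- matrix(dYr, 96L, B)
  dWd <- dA %*% t(ca$Fm)
  db <- rowSums(dA)
  dFm <- t(params$layers[[3L]]$W) %*% dA
  gr <- .trunk_backward(ca$tr, array(dFm, c(params$hidden[2L], N, B)), params)
  gr$layer3 <- list(W = dWd, b = db)
  gr
}

.variant_forward <- function(Q, params) {
  switch(params$variant,
         attention = .attention_forward(Q, params),
         gaussian = .gaussian_forward(Q, params),
         direct = .direct_forward(Q, params))
}

.variant_backward <- function(fw, dY, params) {
  switch(params$variant,
         attention = .attention_backward(fw, dY, params),
         gaussian = .gaussian_backward(fw, dY, params),
         direct = .direct_backward(fw, dY, params))
}

# ---- public chunk / sequence refinement -----------------------------------

#' Refine a single pose chunk
#'
#' Runs the full pipeline of the given refiner variant on one chunk and
#' returns the refined center-frame pose.  For the attention variant this is:
#' positional encoding, convolutional features, affinity softmax, then the
#' shared-weight quaternion mean per joint.
#'
#' @param chunk A [pose_chunk()] whose length matches `params$n_window`.
#' @param params A [refiner_params()] object.
#' @return A 24 x 4 matrix of refined unit quaternions (canonical sign).
#' @export
refine_chunk <- function(chunk, params) {
  stopifnot(inherits(chunk, "pose_chunk"), inherits(params, "refiner_params"))
  N <- dim(chunk$quats)[1L]
  if (N != params$n_window) stop("chunk length must equal params$n_window", call. = FALSE)
  Q <- array(.chunk_internal(chunk), c(4L, 24L, N, 1L))
  fw <- .variant_forward(Q, params)
  quat_canonical(t(matrix(fw$Y, 4L, 24L)))
}

#' Refine a pose sequence with a sliding window
#'
#' Applies the refiner to every window position with stride 1: frames
#' `floor(N/2) + 1` through `T - floor(N/2)` are replaced by refined poses and
#' the `floor(N/2)` boundary frames at each end are copied through unchanged
#' (they never sit at the center of a full window).  The identity vector and
#' frame rate pass through untouched.
#'
#' @param seq A `pose_sequence` with at least `params$n_window` frames.
#' @param params A [refiner_params()] object.
#' @param block Number of windows processed per batched forward pass.
#' @return The refined `pose_sequence`.
#' @export
refine_sequence <- function(seq, params, block = 512L) {
  stopifnot(inherits(seq, "pose_sequence"), inherits(params, "refiner_params"))
  N <- params$n_window
  T_ <- n_frames(seq)
  if (T_ < N) {
    stop(errorCondition(sprintf("sequence too short: %d frames < window %d", T_, N),
                        class = c("sequence_too_short", "error", "condition")))
  }
  half <- (N - 1L) %/% 2L
  Qint <- .seq_internal(seq)                       # (4, 24, T)
  n_win <- T_ - N + 1L
  out <- Qint
  for (start in seq(1L, n_win, by = block)) {
    idx <- start:min(start + block - 1L, n_win)
    B <- length(idx)
    Q <- array(0, c(4L, 24L, N, B))
    for (n in seq_len(N)) Q[, , n, ] <- Qint[, , idx + n - 1L]
    fw <- .variant_forward(Q, params)
    out[, , idx + half] <- fw$Y
  }
  .seq_from_internal(out, beta = seq$beta, fps = seq$fps)
}
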