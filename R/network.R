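# Small neural-network primitives written as explicit forward/backward pairs:
# 1-D convolution (kernel 3, zero padding) realized as an unfold + matrix
# multiply, layer normalization over the channel dimension, ReLU, softmax and
# the Adam optimizer.  Every backward pass is checked against finite
# differences in the test suite.

.LN_EPS <- 1e-5

# (C, N, B) -> (3C, N*B): column t + N(b-1) stacks the kernel-width-3
# receptive field around position t of sample b (zero padded at the ends).
.unfold3 <- function(X) {
  d <- dim(X); C <- d[1L]; N <- d[2L]; B <- d[3L]
  Xp <- array(0, c(C, N + 2L, B))
  Xp[, 2:(N + 1L), ] <- X
  U <- matrix(0, 3L * C, N * B)
  for (k in 1:3) {
    U[((k - 1L) * C + 1L):(k * C), ] <-
      matrix(Xp[, k:(k + N - 1L), , drop = FALSE], C, N * B)
  }
  U
}

# adjoint of .unfold3: (3C, N*B) -> (C, N, B)
.fold3 <- function(dU, C, N, B) {
  dXp <- array(0, c(C, N + 2L, B))
  for (k in 1:3) {
    dXp[, k:(k + N - 1L), ] <- dXp[, k:(k + N - 1L), , drop = FALSE] +
      array(dU[((k - 1L) * C + 1L):(k * C), ], c(C, N, B))
  }
  dXp[, 2:(N + 1L), , drop = FALSE]
}

# layer norm over channels (rows), one statistic per column
.layer_norm_forward <- function(Z, g, b) {
  C <- nrow(Z)
  mu <- colMeans(Z)
  xc <- Z - rep(mu, each = C)
  inv <- 1 / sqrt(colMeans(xc * xc) + .LN_EPS)
  xhat <- xc * rep(inv, each = C)
  out <- xhat * g + b
  list(out = out, xhat = xhat, inv = inv)
}

.layer_norm_backward <- function(cache, dOut, g) {
  C <- nrow(dOut)
  dg <- rowSums(dOut * cache$xhat)
  db <- rowSums(dOut)
  dxhat <- dOut * g
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dZ <- (dxhat - rep(m1, each = C) - cache$xhat * rep(m2, each = C)) *
    rep(cache$inv, each = C)
  list(dZ = dZ, dg = dg, db = db)
}

# conv(k=3, zero pad) -> layer norm -> ReLU on (C_in, N, B); W is an
# (out, in, 3) kernel array, flattened column-major to (out, 3*in).
.conv_block_forward <- function(X, layer) {
  d <- dim(X)
  U <- .unfold3(X)
  Wmat <- matrix(layer$W, dim(layer$W)[1L], 3L * d[1L])
  Z <- Wmat %*% U + layer$b
  ln <- .layer_norm_forward(Z, layer$g, layer$be)
  A <- pmax(ln$out, 0)
  list(A = A, U = U, ln = ln, in_dim = d)
}

# returns parameter grads and (optionally) the input gradient
.conv_block_backward <- function(cache, dA, layer, need_input_grad = TRUE) {
  dLn <- dA * (cache$ln$out > 0)
  lb <- .layer_norm_backward(cache$ln, dLn, layer$g)
  dW <- array(lb$dZ %*% t(cache$U), dim(layer$W))
  db <- rowSums(lb$dZ)
  dX <- NULL
  if (need_input_grad) {
    Wmat <- matrix(layer$W, dim(layer$W)[1L], 3L * cache$in_dim[1L])
    dU <- t(Wmat) %*% lb$dZ
    dX <- .fold3(dU, cache$in_dim[1L], cache$in_dim[2L], cache$in_dim[3L])
  }
  list(dX = dX, grads = list(W = dW, b = db, g = lb$dg, be = lb$db))
}

.softmax_cols <- function(L) {
  Z <- sweep(L, 2L, apply(L, 2L, max))
  E <- exp(Z)
  sweep(E, 2L, colSums(E), "/")
}

.softmax_cols_backward <- function(W, dW) {
  W * sweep(dW, 2L, colSums(W * dW))
}

.glorot <- function(nout, nin, k = 1L) {
  lim <- sqrt(6 / (nin * k + nout * k))
  array(stats::runif(nout * nin * k, -lim, lim),
        if (k > 1L) c(nout, nin, k) else c(nout, nin))
}

# ---- Adam ----------------------------------------------------------------

.adam_init <- function(grads_shape) {
  lapply(grads_shape, function(x) list(m = array(0, dim(x) %||% length(x)),
                                       v = array(0, dim(x) %||% length(x))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one Adam step over a flat named list of arrays; returns updated params+state
.adam_step <- function(params_flat, grads_flat, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8, t = 1L) {
  for (nm in names(params_flat)) {
    g <- grads_flat[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params_flat[[nm]] <- params_flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params_flat, state = state)
}

# flatten refiner params into a named list of arrays (layer1.W, layer1.b, ...)
.params_flatten <- function(params) {
  out <- list()
  for (l in seq_along(params$layers)) {
    for (nm in names(params$layers[[l]])) {
      out[[paste0("layer", l, ".", nm)]] <- params$layers[[l]][[nm]]
    }
  }
  out
}

.params_unflatten <- function(params, flat) {
  for (l in seq_along(params$layers)) {
    for (nm in names(params$layers[[l]])) {
      key <- paste0("layer", l, ".", nm)
      dm <- dim(params$layers[[l]][[nm]])
      params$layers[[l]][[nm]] <- if (is.null(dm)) as.numeric(flat[[key]])
      else array(flat[[key]], dm)
    }
  }
  params
}
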