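# Minimal neural-network primitives for the keyword-selector
# architectures: time-distributed sigmoid outputs over a dense, LSTM or
# 1-d convolutional encoder, with an optional POS-tag branch encoded by
# a small rectifier layer. Written in vectorised base R (forward and
# backward passes, Adam updates); sizes are small enough that no
# compiled framework is needed, and everything is deterministic under a
# fixed seed.

sigmoid <- function(x) 1 / (1 + exp(-x))

rand_mat <- function(nr, nc, scale = NULL) {
  scale <- scale %||% sqrt(1 / nr)
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}

# ---- LSTM layer -------------------------------------------------------

lstm_init <- function(din, h) {
  list(Wx = rand_mat(din, 4L * h), Wh = rand_mat(h, 4L * h),
       b = matrix(0, 1L, 4L * h))
}

# Xl: list over T of (n x din); returns Hl list of (n x h) + cache
lstm_forward <- function(params, Xl, h) {
  n <- nrow(Xl[[1L]]); T_ <- length(Xl)
  Hl <- vector("list", T_)
  cache <- vector("list", T_)
  h_prev <- matrix(0, n, h); c_prev <- matrix(0, n, h)
  for (t in seq_len(T_)) {
    A <- Xl[[t]] %*% params$Wx + h_prev %*% params$Wh +
      matrix(params$b, n, 4L * h, byrow = TRUE)
    i_g <- sigmoid(A[, 1:h, drop = FALSE])
    f_g <- sigmoid(A[, (h + 1L):(2L * h), drop = FALSE])
    o_g <- sigmoid(A[, (2L * h + 1L):(3L * h), drop = FALSE])
    g_g <- tanh(A[, (3L * h + 1L):(4L * h), drop = FALSE])
    c_t <- f_g * c_prev + i_g * g_g
    tc <- tanh(c_t)
    h_t <- o_g * tc
    cache[[t]] <- list(i = i_g, f = f_g, o = o_g, g = g_g, c = c_t,
                       c_prev = c_prev, h_prev = h_prev, tc = tc,
                       x = Xl[[t]])
    Hl[[t]] <- h_t
    h_prev <- h_t; c_prev <- c_t
  }
  list(H = Hl, cache = cache)
}

# dHl: list over T of (n x h) upstream gradients
lstm_backward <- function(params, fwd, dHl, h) {
  T_ <- length(dHl)
  n <- nrow(dHl[[1L]])
  dWx <- params$Wx * 0; dWh <- params$Wh * 0; db <- params$b * 0
  dh_next <- matrix(0, n, h); dc_next <- matrix(0, n, h)
  dXl <- vector("list", T_)
  for (t in rev(seq_len(T_))) {
    cc <- fwd$cache[[t]]
    dh <- dHl[[t]] + dh_next
    do_g <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dA <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_g * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dWx <- dWx + crossprod(cc$x, dA)
    dWh <- dWh + crossprod(cc$h_prev, dA)
    db <- db + colSums(dA)
    dXl[[t]] <- tcrossprod(dA, params$Wx)
    dh_next <- tcrossprod(dA, params$Wh)
    dc_next <- dc * cc$f
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dX = dXl)
}

# ---- time-distributed dense / conv primitives -------------------------

td_dense_init <- function(din, dout) {
  list(W = rand_mat(din, dout), b = matrix(0, 1L, dout))
}

td_dense_forward <- function(params, Xl, relu = FALSE) {
  n <- nrow(Xl[[1L]])
  out <- lapply(Xl, function(x) {
    z <- x %*% params$W + matrix(params$b, n, ncol(params$W), byrow = TRUE)
    if (relu) pmax(z, 0) else z
  })
  list(Z = out, X = Xl, relu = relu)
}

td_dense_backward <- function(params, fwd, dZl) {
  dW <- params$W * 0; db <- params$b * 0
  dXl <- vector("list", length(dZl))
  for (t in seq_along(dZl)) {
    dz <- dZl[[t]]
    if (fwd$relu) dz <- dz * (fwd$Z[[t]] > 0)
    dW <- dW + crossprod(fwd$X[[t]], dz)
    db <- db + colSums(dz)
    dXl[[t]] <- tcrossprod(dz, params$W)
  }
  list(grads = list(W = dW, b = db), dX = dXl)
}

conv1d_init <- function(din, filters) {
  list(W1 = rand_mat(din, filters), W2 = rand_mat(din, filters),
       W3 = rand_mat(din, filters), b = matrix(0, 1L, filters))
}

conv1d_forward <- function(params, Xl) {
  T_ <- length(Xl); n <- nrow(Xl[[1L]])
  zero <- matrix(0, n, ncol(Xl[[1L]]))
  S <- vector("list", T_)
  for (t in seq_len(T_)) {
    xm <- if (t > 1L) Xl[[t - 1L]] else zero
    xp <- if (t < T_) Xl[[t + 1L]] else zero
    S[[t]] <- xm %*% params$W1 + Xl[[t]] %*% params$W2 + xp %*% params$W3 +
      matrix(params$b, n, ncol(params$W1), byrow = TRUE)
  }
  list(Z = lapply(S, function(s) pmax(s, 0)), S = S, X = Xl)
}

conv1d_backward <- function(params, fwd, dZl) {
  T_ <- length(dZl); n <- nrow(dZl[[1L]])
  zero <- matrix(0, n, nrow(params$W1))
  dW1 <- params$W1 * 0; dW2 <- params$W2 * 0; dW3 <- params$W3 * 0
  db <- params$b * 0
  for (t in seq_len(T_)) {
    ds <- dZl[[t]] * (fwd$S[[t]] > 0)
    xm <- if (t > 1L) fwd$X[[t - 1L]] else zero
    xp <- if (t < T_) fwd$X[[t + 1L]] else zero
    dW1 <- dW1 + crossprod(xm, ds)
    dW2 <- dW2 + crossprod(fwd$X[[t]], ds)
    dW3 <- dW3 + crossprod(xp, ds)
    db <- db + colSums(ds)
  }
  list(grads = list(W1 = dW1, W2 = dW2, W3 = dW3, b = db))
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "list", classes = "ANY")
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (k in names(params)) {
    if (is.list(params[[k]]) && !is.matrix(params[[k]])) {
      upd <- adam_step(params[[k]], grads[[k]], state[[k]], lr, t,
                       beta1, beta2, eps)
      params[[k]] <- upd$params; state[[k]] <- upd$state
    } else {
      st <- state[[k]]
      st$m <- beta1 * st$m + (1 - beta1) * grads[[k]]
      st$v <- beta2 * st$v + (1 - beta2) * grads[[k]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
      state[[k]] <- st
    }
  }
  list(params = params, state = state)
}

# ---- batch helpers ----------------------------------------------------

# slice an (n,T,D) array into a list over T of (nb x D) matrices
array_to_list <- function(X, idx) {
  T_ <- dim(X)[2L]; D <- dim(X)[3L]
  lapply(seq_len(T_), function(t)
    matrix(X[idx, t, ], nrow = length(idx), ncol = D))
}

pos_onehot_list <- function(POS, idx, n_tags) {
  T_ <- ncol(POS)
  lapply(seq_len(T_), function(t) {
    m <- matrix(0, length(idx), n_tags)
    m[cbind(seq_along(idx), POS[idx, t])] <- 1
    m
  })
}

dropout_mask <- function(n, d, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(n * d, 1L, 1 - p) / (1 - p), n, d)
}
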