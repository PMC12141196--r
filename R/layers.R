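# Low-level network primitives shared by the encoders, the cross-attention
# modules and the fusion classifier. All batch tensors are base-R arrays with
# the sample index first: a set of k group vectors of dimension s for a batch
# of n samples is an n x k x s array. Backward passes return gradients in the
# same nested-list layout as the parameters so a generic Adam step can walk
# them.

# ---- fully connected stack: affine + ReLU per layer ----

fcn_init <- function(sizes) {
  # sizes: c(d_in, h1, ..., d_out); weights stored as d_in x d_out so that
  # forward is X %*% W + b
  layers <- vector("list", length(sizes) - 1L)
  for (i in seq_along(layers)) {
    layers[[i]] <- list(W = glorot(sizes[i], sizes[i + 1L]),
                        b = numeric(sizes[i + 1L]))
  }
  layers
}

fcn_forward <- function(X, layers, final_relu = TRUE) {
  acts <- vector("list", length(layers) + 1L)
  pre <- vector("list", length(layers))
  acts[[1L]] <- X
  for (i in seq_along(layers)) {
    Z <- sweep(acts[[i]] %*% layers[[i]]$W, 2L, layers[[i]]$b, "+")
    pre[[i]] <- Z
    acts[[i + 1L]] <- if (final_relu || i < length(layers)) relu(Z) else Z
  }
  list(out = acts[[length(acts)]],
       cache = list(acts = acts, pre = pre, final_relu = final_relu))
}

fcn_backward <- function(dout, cache, layers) {
  grads <- vector("list", length(layers))
  d <- dout
  for (i in rev(seq_along(layers))) {
    if (cache$final_relu || i < length(layers)) {
      d <- d * (cache$pre[[i]] > 0)
    }
    grads[[i]] <- list(W = crossprod(cache$acts[[i]], d), b = colSums(d))
    d <- d %*% t(layers[[i]]$W)
  }
  list(dX = d, grads = grads)
}

# ---- layer normalization over the last (embedding) axis ----

layernorm_init <- function(s) list(gamma = rep(1, s), beta = numeric(s))

layernorm_forward <- function(U, pars, eps = 1e-5) {
  d <- dim(U)
  n <- d[1L]; k <- d[2L]; s <- d[3L]
  X <- matrix(U, n * k, s)             # (sample, group) rows
  mu <- rowMeans(X)
  Xc <- X - mu
  inv <- 1 / sqrt(rowMeans(Xc^2) + eps)
  xhat <- Xc * inv
  Y <- sweep(xhat, 2L, pars$gamma, "*") +
    matrix(pars$beta, n * k, s, byrow = TRUE)
  list(out = array(Y, d),
       cache = list(xhat = xhat, inv_sd = inv, dims = d, eps = eps))
}

layernorm_backward <- function(dout, cache, pars) {
  d <- cache$dims
  s <- d[3L]
  dy <- matrix(dout, d[1L] * d[2L], s)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, pars$gamma, "*")
  # standard layer-norm backward per (sample, group) row
  dx <- cache$inv_sd / s * (s * dxhat - rowSums(dxhat) -
                              xhat * rowSums(dxhat * xhat))
  list(dU = array(dx, d), grads = list(gamma = dgamma, beta = dbeta))
}

# ---- scaled dot-product attention over group axes ----

# Project an n x k x s array by a s x l matrix, group-wise. All groups share
# W, so the (sample, group) pairs stack into one matrix product.
proj_groups <- function(U, W) {
  d <- dim(U)
  array(matrix(U, d[1L] * d[2L], d[3L]) %*% W, c(d[1L], d[2L], ncol(W)))
}

# Gradients of a shared group-wise projection: given dOut (n x k x l) and the
# input U (n x k x s), return dW (s x l) and dU contribution (n x k x s).
proj_groups_backward <- function(dOut, U, W) {
  d <- dim(U)
  Um <- matrix(U, d[1L] * d[2L], d[3L])
  Dm <- matrix(dOut, d[1L] * d[2L], ncol(W))
  list(dW = crossprod(Um, Dm),
       dU = array(Dm %*% t(W), d))
}

# Attention core for one head. Q: n x kq x l, K/V: n x kk x l.
# Returns out (n x kq x l) and attention A (n x kq x kk). The (sample, query
# group) pairs are flattened into one matrix axis so the loops run over the
# source groups only.
attn_head_forward <- function(Q, K, V, scale) {
  n <- dim(Q)[1L]; kq <- dim(Q)[2L]; kk <- dim(K)[2L]; l <- dim(Q)[3L]
  Qm <- matrix(Q, n * kq, l)             # rows indexed by (sample, query)
  L <- matrix(0, n * kq, kk)
  rep_idx <- rep(seq_len(n), kq)
  for (q in seq_len(kk)) {
    L[, q] <- rowSums(Qm * slab(K, q)[rep_idx, , drop = FALSE]) / scale
  }
  Am <- softmax_rows(L)                  # (n*kq) x kk
  Om <- matrix(0, n * kq, l)
  for (q in seq_len(kk)) {
    Om <- Om + Am[, q] * slab(V, q)[rep_idx, , drop = FALSE]
  }
  list(out = array(Om, c(n, kq, l)), A = array(Am, c(n, kq, kk)))
}

attn_head_backward <- function(dout, Q, K, V, A, scale) {
  n <- dim(Q)[1L]; kq <- dim(Q)[2L]; kk <- dim(K)[2L]; l <- dim(Q)[3L]
  rep_idx <- rep(seq_len(n), kq)
  dOm <- matrix(dout, n * kq, l)
  Am <- matrix(A, n * kq, kk)
  dAm <- matrix(0, n * kq, kk)
  dV <- array(0, dim(V))
  for (q in seq_len(kk)) {
    Vq <- slab(V, q)[rep_idx, , drop = FALSE]
    dAm[, q] <- rowSums(dOm * Vq)
    # scatter-add the (sample, query) contributions back to sample rows
    dVq <- rowsum(Am[, q] * dOm, rep_idx)
    dV[, q, ] <- slab(dV, q) + dVq
  }
  dLm <- softmax_rows_backward(dAm, Am) / scale
  Qm <- matrix(Q, n * kq, l)
  dQm <- matrix(0, n * kq, l)
  dK <- array(0, dim(K))
  for (q in seq_len(kk)) {
    dQm <- dQm + dLm[, q] * slab(K, q)[rep_idx, , drop = FALSE]
    dK[, q, ] <- slab(dK, q) + rowsum(dLm[, q] * Qm, rep_idx)
  }
  list(dQ = array(dQm, c(n, kq, l)), dK = dK, dV = dV)
}

# ---- multi-head self-attention over a set of group vectors ----
# Heads are concatenated back to s dimensions; no output projection, no
# residual (those belong to the cross-attention modules only).

mhsa_init <- function(s, H) {
  if (s %% H != 0L) abort_("embedding size ", s, " not divisible by ", H, " heads")
  l <- s %/% H
  list(heads = lapply(seq_len(H), function(h) {
    list(Wq = glorot(s, l), Wk = glorot(s, l), Wv = glorot(s, l))
  }))
}

mhsa_forward <- function(U, pars, scale) {
  d <- dim(U)
  H <- length(pars$heads)
  l <- d[3L] %/% H
  out <- array(0, c(d[1L], d[2L], d[3L]))
  hc <- vector("list", H)
  for (h in seq_len(H)) {
    ph <- pars$heads[[h]]
    Q <- proj_groups(U, ph$Wq)
    K <- proj_groups(U, ph$Wk)
    V <- proj_groups(U, ph$Wv)
    att <- attn_head_forward(Q, K, V, scale)
    cols <- ((h - 1L) * l + 1L):(h * l)
    out[, , cols] <- att$out
    hc[[h]] <- list(Q = Q, K = K, V = V, A = att$A)
  }
  list(out = out, cache = list(U = U, heads = hc, scale = scale, l = l))
}

mhsa_backward <- function(dout, cache, pars) {
  U <- cache$U
  d <- dim(U)
  H <- length(pars$heads)
  l <- cache$l
  dU <- array(0, d)
  grads <- list(heads = vector("list", H))
  for (h in seq_len(H)) {
    ph <- pars$heads[[h]]
    hc <- cache$heads[[h]]
    cols <- ((h - 1L) * l + 1L):(h * l)
    dOh <- array(dout[, , cols], c(d[1L], d[2L], l))
    bk <- attn_head_backward(dOh, hc$Q, hc$K, hc$V, hc$A, cache$scale)
    bq <- proj_groups_backward(bk$dQ, U, ph$Wq)
    bkk <- proj_groups_backward(bk$dK, U, ph$Wk)
    bv <- proj_groups_backward(bk$dV, U, ph$Wv)
    grads$heads[[h]] <- list(Wq = bq$dW, Wk = bkk$dW, Wv = bv$dW)
    dU <- dU + bq$dU + bkk$dU + bv$dU
  }
  list(dU = dU, grads = grads)
}
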