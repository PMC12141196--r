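# Independent loop-based reference implementations of the encoder and the
# cross-attention module, shared by the unit and acceptance tests. They use
# explicit per-group loops and share no code with the package internals.

# Independent brute-force reference for the grouped encoder: explicit loops
# over the per-group FCN and the multi-head self-attention, no shared code
# with the implementation under test.
oracle_encode <- function(x, partition, fcn, heads, s, scale) {
  k <- partition$k
  xprime <- vector("list", k)
  for (g in seq_len(k)) {
    v <- x[partition$assignment[[g]]]
    for (layer in fcn[[g]]) {
      z <- as.numeric(t(layer$W) %*% v) + layer$b
      v <- pmax(z, 0)
    }
    xprime[[g]] <- v
  }
  H <- length(heads)
  l <- s / H
  U <- matrix(0, k, s)
  for (h in seq_len(H)) {
    ph <- heads[[h]]
    Q <- lapply(xprime, function(v) as.numeric(t(ph$Wq) %*% v))
    K <- lapply(xprime, function(v) as.numeric(t(ph$Wk) %*% v))
    V <- lapply(xprime, function(v) as.numeric(t(ph$Wv) %*% v))
    for (p in seq_len(k)) {
      logits <- sapply(seq_len(k), function(q) sum(Q[[p]] * K[[q]]) / scale)
      e <- exp(logits - max(logits))
      a <- e / sum(e)
      out <- numeric(l)
      for (q in seq_len(k)) out <- out + a[q] * V[[q]]
      U[p, (h - 1) * l + seq_len(l)] <- out
    }
  }
  U
}

# Loop-based reference for one cross-attention edge (Z = heads fused by W^O
# plus residual, inputs layer-normalized), independent of the implementation.
oracle_cross <- function(Us, Ut, ca, ln_eps = 1e-5) {
  norm1 <- function(v, g, b) {
    mu <- mean(v); sd2 <- mean((v - mu)^2)
    g * (v - mu) / sqrt(sd2 + ln_eps) + b
  }
  p <- ca$params
  Us_n <- Us; Ut_n <- Ut
  if (ca$layernorm) {
    for (q in seq_len(nrow(Us))) Us_n[q, ] <- norm1(Us[q, ], p$ln_src$gamma, p$ln_src$beta)
    for (q in seq_len(nrow(Ut))) Ut_n[q, ] <- norm1(Ut[q, ], p$ln_tgt$gamma, p$ln_tgt$beta)
  }
  kj <- nrow(Ut); ki <- nrow(Us); H <- ca$heads; l <- ca$l
  O <- matrix(0, kj, H * l)
  for (h in seq_len(H)) {
    ph <- p$heads[[h]]
    for (pp in seq_len(kj)) {
      qv <- as.numeric(t(ph$Wq) %*% Ut_n[pp, ])
      logits <- sapply(seq_len(ki), function(q) {
        sum(qv * as.numeric(t(ph$Wk) %*% Us_n[q, ])) / ca$scale_val
      })
      e <- exp(logits - max(logits)); a <- e / sum(e)
      out <- numeric(l)
      for (q in seq_len(ki)) out <- out + a[q] * as.numeric(t(ph$Wv) %*% Us_n[q, ])
      O[pp, (h - 1) * l + seq_len(l)] <- out
    }
  }
  O %*% p$Wo + Ut
}
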