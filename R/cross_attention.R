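#' Initialize a cross-attention module for one interaction edge
#'
#' For an edge source -> target, each of the target's `k_j` group embeddings
#' attends over the source's `k_i` group embeddings with `H` heads. Per head,
#' queries come from the target (`s_j -> l_j`), keys and values from the
#' source (`s_i -> l_j`), with `l_j = s_j / H`. Head outputs are concatenated
#' and fused by a projection `W^O` back to `s_j` dimensions; a residual
#' connection adds the (pre-normalization) target embeddings, and both inputs
#' are layer-normalized before the attention.
#'
#' The attention logits are divided by `s_j` by default (`scale = "sj"`);
#' `"sqrt_sj"` and `"sqrt_lj"` give the usual square-root variants.
#'
#' @param s_src Source embedding dimension `s_i`.
#' @param s_tgt Target embedding dimension `s_j`; must be divisible by `heads`.
#' @param heads Number of cross-attention heads `H`.
#' @param scale One of `"sj"`, `"sqrt_sj"`, `"sqrt_lj"`.
#' @param layernorm Apply layer normalization to the inputs (default TRUE)?
#' @param seed Integer seed for weight initialization.
#' @param edge Optional character pair `c(source, target)` for bookkeeping.
#'
#' @return An object of class `cross_attention` with per-head `Wq`, `Wk`,
#'   `Wv`, the head-fusion matrix `Wo`, and layer-norm parameters.
#' @export
cross_attention_init <- function(s_src, s_tgt, heads = 2L,
                                 scale = c("sj", "sqrt_sj", "sqrt_lj"),
                                 layernorm = TRUE, seed = 1L, edge = NULL) {
  scale <- match.arg(scale)
  if (s_tgt %% heads != 0L) {
    abort_("s_tgt = ", s_tgt, " must be divisible by heads = ", heads)
  }
  l <- s_tgt %/% heads
  scale_val <- switch(scale, sj = s_tgt, sqrt_sj = sqrt(s_tgt),
                      sqrt_lj = sqrt(l))
  with_seed_(seed, {
    params <- list(
      heads = lapply(seq_len(heads), function(h) {
        list(Wq = glorot(s_tgt, l), Wk = glorot(s_src, l),
             Wv = glorot(s_src, l))
      }),
      Wo = glorot(s_tgt, s_tgt)
    )
    if (layernorm) {
      params$ln_src <- layernorm_init(s_src)
      params$ln_tgt <- layernorm_init(s_tgt)
    }
    structure(list(edge = edge, params = params, s_src = s_src,
                   s_tgt = s_tgt, heads = heads, l = l,
                   scale = scale, scale_val = scale_val,
                   layernorm = layernorm),
              class = "cross_attention")
  })
}

# Batch forward. U_src: n x k_i x s_i, U_tgt: n x k_j x s_j.
cross_attend_batch <- function(U_src, U_tgt, ca, keep_cache = FALSE) {
  if (dim(U_src)[2L] == 0L || dim(U_tgt)[2L] == 0L) {
    abort_("cross-attention requires at least one group per modality")
  }
  n <- dim(U_tgt)[1L]; kj <- dim(U_tgt)[2L]; sj <- dim(U_tgt)[3L]
  p <- ca$params
  if (ca$layernorm) {
    lns <- layernorm_forward(U_src, p$ln_src)
    lnt <- layernorm_forward(U_tgt, p$ln_tgt)
    Us <- lns$out; Ut <- lnt$out
  } else {
    lns <- lnt <- NULL
    Us <- U_src; Ut <- U_tgt
  }
  H <- ca$heads; l <- ca$l
  O <- array(0, c(n, kj, sj))
  hc <- vector("list", H)
  for (h in seq_len(H)) {
    ph <- p$heads[[h]]
    Q <- proj_groups(Ut, ph$Wq)
    K <- proj_groups(Us, ph$Wk)
    V <- proj_groups(Us, ph$Wv)
    att <- attn_head_forward(Q, K, V, ca$scale_val)
    O[, , ((h - 1L) * l + 1L):(h * l)] <- att$out
    hc[[h]] <- list(Q = Q, K = K, V = V, A = att$A)
  }
  # head fusion + residual with pre-normalization target values
  CAout <- proj_groups(O, p$Wo)
  Z <- U_tgt + CAout
  cache <- if (keep_cache) {
    list(U_src = U_src, U_tgt = U_tgt, Us = Us, Ut = Ut,
         ln_src = lns, ln_tgt = lnt, heads = hc, O = O, CAout = CAout)
  } else {
    NULL
  }
  list(Z = Z, A = lapply(hc, `[[`, "A"), cache = cache)
}

cross_attend_backward <- function(dZ, cache, ca) {
  p <- ca$params
  n <- dim(dZ)[1L]; kj <- dim(dZ)[2L]; sj <- dim(dZ)[3L]
  H <- ca$heads; l <- ca$l
  dU_tgt <- dZ  # residual path
  bo <- proj_groups_backward(dZ, cache$O, p$Wo)
  dO <- bo$dU
  dUs <- array(0, dim(cache$Us))
  dUt <- array(0, dim(cache$Ut))
  grads <- list(heads = vector("list", H), Wo = bo$dW)
  for (h in seq_len(H)) {
    ph <- p$heads[[h]]
    hc <- cache$heads[[h]]
    dOh <- array(dO[, , ((h - 1L) * l + 1L):(h * l)], c(n, kj, l))
    bk <- attn_head_backward(dOh, hc$Q, hc$K, hc$V, hc$A, ca$scale_val)
    bq <- proj_groups_backward(bk$dQ, cache$Ut, ph$Wq)
    bkk <- proj_groups_backward(bk$dK, cache$Us, ph$Wk)
    bv <- proj_groups_backward(bk$dV, cache$Us, ph$Wv)
    grads$heads[[h]] <- list(Wq = bq$dW, Wk = bkk$dW, Wv = bv$dW)
    dUt <- dUt + bq$dU
    dUs <- dUs + bkk$dU + bv$dU
  }
  if (ca$layernorm) {
    bs <- layernorm_backward(dUs, cache$ln_src$cache, p$ln_src)
    bt <- layernorm_backward(dUt, cache$ln_tgt$cache, p$ln_tgt)
    grads$ln_src <- bs$grads
    grads$ln_tgt <- bt$grads
    dU_src <- bs$dU
    dU_tgt <- dU_tgt + bt$dU
  } else {
    dU_src <- dUs
    dU_tgt <- dU_tgt + dUt
  }
  list(dU_src = dU_src, dU_tgt = dU_tgt, grads = grads)
}

#' Cross-modal embedding of a target modality enriched by a source modality
#'
#' Computes the embedding `Z` for one interaction edge: the target's group
#' embeddings attend over the source's group embeddings with `H` heads, head
#' outputs are fused by `W^O` and a residual connection adds the original
#' target embeddings. `Z` always has the target's group count.
#'
#' @param U_source `encoded_modality` (or k_i x s_i matrix) for the source.
#' @param U_target `encoded_modality` (or k_j x s_j matrix) for the target.
#' @param ca A [cross_attention_init()] module.
#' @param keep_attention Retain the per-head attention matrices?
#'
#' @return An object of class `cross_modal_embedding`: list with `edge`, `Z`
#'   (k_j x s_j matrix) and optionally `A` (list per head of k_j x k_i
#'   row-stochastic matrices).
#' @export
cross_attend <- function(U_source, U_target, ca, keep_attention = TRUE) {
  Us <- if (inherits(U_source, "encoded_modality")) U_source$U else U_source
  Ut <- if (inherits(U_target, "encoded_modality")) U_target$U else U_target
  if (ncol(Us) != ca$s_src || ncol(Ut) != ca$s_tgt) {
    abort_("embedding dimensions (", ncol(Us), ", ", ncol(Ut),
           ") do not match module (", ca$s_src, ", ", ca$s_tgt, ")")
  }
  aS <- array(0, c(1L, nrow(Us), ncol(Us))); aS[1L, , ] <- Us
  aT <- array(0, c(1L, nrow(Ut), ncol(Ut))); aT[1L, , ] <- Ut
  fw <- cross_attend_batch(aS, aT, ca)
  out <- list(edge = ca$edge, Z = matrix(fw$Z[1L, , ], nrow(Ut), ncol(Ut)))
  if (keep_attention) {
    out$A <- lapply(fw$A, function(A) matrix(A[1L, , ], nrow(Ut), nrow(Us)))
  }
  structure(out, class = "cross_modal_embedding")
}
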