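#' Randomly partition features into near-equal groups
#'
#' High-dimensional omics vectors are split into `k` random groups before
#' encoding so that attention is computed over groups rather than individual
#' features, keeping the attention matrices tractable. A seeded random
#' permutation of the feature indices is chunked into `k` groups whose sizes
#' differ by at most one. The partition is stored with the model so training
#' and inference use the same grouping.
#'
#' @param p Number of features.
#' @param k Number of groups, `1 <= k <= p`.
#' @param seed Integer seed for the permutation (independent of the training
#'   seed).
#' @param modality_name Optional modality name carried for bookkeeping.
#'
#' @return An object of class `group_partition`: list with `k`, `assignment`
#'   (list of k integer vectors partitioning `1:p`), `p`, `seed`,
#'   `modality_name`.
#' @export
make_partition <- function(p, k, seed = 1L, modality_name = NULL) {
  if (k < 1L || k > p) abort_("need 1 <= k <= p, got k = ", k, ", p = ", p)
  sizes <- rep(p %/% k, k)
  extra <- p %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  perm <- with_seed_(seed, sample.int(p))
  assignment <- split(perm, rep(seq_len(k), times = sizes))
  names(assignment) <- NULL
  structure(list(modality_name = modality_name, k = k, p = p,
                 assignment = assignment, seed = seed),
            class = "group_partition")
}

# Default per-group FCN widths: p/k -> 2s -> s (two ReLU layers).
default_fcn_sizes <- function(group_size, s, fcn_hidden = NULL) {
  c(group_size, fcn_hidden %||% (2L * s), s)
}

#' Initialize a grouped-attention modality encoder
#'
#' The encoder maps one modality's feature vector to `k` group embeddings of
#' dimension `s`: each group's features pass through an unshared fully
#' connected stack (affine + ReLU layers), then multi-head self-attention over
#' the groups lets every group attend to every other, and the heads are
#' concatenated back to `s` dimensions.
#'
#' @param partition A [make_partition()] object.
#' @param s Group embedding dimension; must be divisible by `heads`.
#' @param heads Number of self-attention heads.
#' @param fcn_hidden Hidden width of the per-group FCN (default `2 * s`).
#' @param seed Integer seed for weight initialization.
#'
#' @return An object of class `modality_encoder` holding the partition, the
#'   per-group FCN weights and the attention projections.
#' @export
encoder_init <- function(partition, s = 16L, heads = 2L, fcn_hidden = NULL,
                         seed = 1L) {
  if (s %% heads != 0L) abort_("s = ", s, " must be divisible by heads = ", heads)
  with_seed_(seed, {
    fcn <- lapply(partition$assignment, function(idx) {
      fcn_init(default_fcn_sizes(length(idx), s, fcn_hidden))
    })
    attn <- mhsa_init(s, heads)
    structure(list(modality_name = partition$modality_name,
                   partition = partition,
                   params = list(fcn = fcn, attn = attn),
                   s = s, heads = heads,
                   scale = sqrt(s / heads)),
              class = "modality_encoder")
  })
}

# Batch forward: X is an n x p matrix of standardized features.
encode_batch <- function(X, encoder, keep_cache = FALSE) {
  part <- encoder$partition
  n <- nrow(X)
  if (ncol(X) != part$p) {
    abort_("encoder for '", encoder$modality_name %||% "?", "' expects ",
           part$p, " features, got ", ncol(X))
  }
  if (!all(is.finite(X))) abort_("non-finite value in encoder input")
  k <- part$k
  U0 <- array(0, c(n, k, encoder$s))
  fcn_caches <- vector("list", k)
  for (g in seq_len(k)) {
    fw <- fcn_forward(X[, part$assignment[[g]], drop = FALSE],
                      encoder$params$fcn[[g]])
    U0 <- set_slab(U0, g, fw$out)
    fcn_caches[[g]] <- fw$cache
  }
  att <- mhsa_forward(U0, encoder$params$attn, encoder$scale)
  cache <- if (keep_cache) list(fcn = fcn_caches, attn = att$cache) else NULL
  list(U = att$out, A = lapply(att$cache$heads, `[[`, "A"), cache = cache)
}

encoder_backward <- function(dU, cache, encoder) {
  bk <- mhsa_backward(dU, cache$attn, encoder$params$attn)
  k <- encoder$partition$k
  fcn_grads <- vector("list", k)
  for (g in seq_len(k)) {
    fb <- fcn_backward(slab(bk$dU, g), cache$fcn[[g]],
                       encoder$params$fcn[[g]])
    fcn_grads[[g]] <- fb$grads
  }
  list(fcn = fcn_grads, attn = bk$grads)
}

#' Encode one modality sample into group embeddings
#'
#' @param x Numeric feature vector of length `p` (standardized scale).
#' @param encoder A [encoder_init()] object (typically trained).
#' @param keep_attention Retain the per-head attention matrices for
#'   diagnostics?
#'
#' @return An object of class `encoded_modality`: list with `modality_name`,
#'   `U` (k x s matrix of group embeddings) and optionally `attention` (list
#'   per head of k x k row-stochastic matrices).
#' @export
encode <- function(x, encoder, keep_attention = FALSE) {
  X <- matrix(as.numeric(x), nrow = 1L)
  fw <- encode_batch(X, encoder)
  U <- matrix(fw$U[1L, , ], encoder$partition$k, encoder$s)
  out <- list(modality_name = encoder$modality_name, U = U)
  if (keep_attention) {
    out$attention <- lapply(fw$A, function(A) {
      matrix(A[1L, , ], dim(A)[2L], dim(A)[3L])
    })
  }
  structure(out, class = "encoded_modality")
}

# ---- phase-1 unimodal classification head ----

unimodal_head_init <- function(k, s, C) {
  list(W = glorot(k * s, C), b = numeric(C))
}

# U_batch: n x k x s -> logits n x C
head_logits_batch <- function(U_batch, head) {
  d <- dim(U_batch)
  Uflat <- matrix(U_batch, d[1L], d[2L] * d[3L])
  sweep(Uflat %*% head$W, 2L, head$b, "+")
}

#' Class probabilities from a unimodal encoder head
#'
#' A single affine layer (one neuron per class) with softmax, used to train
#' each encoder individually in phase 1 and as the unimodal baseline.
#'
#' @param encoded An `encoded_modality` (from [encode()]) or a k x s matrix.
#' @param head Head parameters (`W`: (k*s) x C, `b`: length C).
#' @return Numeric probability vector of length C (non-negative, sums to 1).
#' @export
unimodal_head_predict <- function(encoded, head) {
  U <- if (inherits(encoded, "encoded_modality")) encoded$U else encoded
  u <- as.numeric(U)
  if (length(u) != nrow(head$W)) {
    abort_("head expects input of length ", nrow(head$W), ", got ", length(u))
  }
  logits <- drop(u %*% head$W) + head$b
  as.numeric(softmax_rows(matrix(logits, 1L)))
}
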