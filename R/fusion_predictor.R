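# Fusion classifier: per-target multimodal branches enriched by MHSA,
# concatenated with zero-in-degree unimodal branches, then an FCN + softmax.

# Flatten an n x k x s array into n x (k*s), group-blocked: columns
# (g-1)*s + 1:s hold group g. The inverse of unflatten_groups().
flatten_groups <- function(U) {
  d <- dim(U)
  out <- matrix(0, d[1L], d[2L] * d[3L])
  for (g in seq_len(d[2L])) out[, (g - 1L) * d[3L] + seq_len(d[3L])] <- slab(U, g)
  out
}

unflatten_groups <- function(M, k, s) {
  out <- array(0, c(nrow(M), k, s))
  for (g in seq_len(k)) out <- set_slab(out, g, M[, (g - 1L) * s + seq_len(s),
                                                  drop = FALSE])
  out
}

# Concatenate a list of n x k_e x s arrays along the group axis.
bind_groups <- function(arrays) {
  n <- dim(arrays[[1L]])[1L]
  s <- dim(arrays[[1L]])[3L]
  m <- sum(vapply(arrays, function(a) dim(a)[2L], 0L))
  out <- array(0, c(n, m, s))
  at <- 0L
  for (a in arrays) {
    for (g in seq_len(dim(a)[2L])) out <- set_slab(out, at + g, slab(a, g))
    at <- at + dim(a)[2L]
  }
  out
}

branch_init <- function(s, heads, m) {
  list(attn = mhsa_init(s, heads), s = s, heads = heads, m = m,
       scale = sqrt(s / heads))
}

# Batch forward of one multimodal branch given the per-edge embeddings
# (list of n x k_j x s_j arrays in edge order) and the target's encoding.
# The ensemble over which MHSA runs always contains the target's groups;
# include_target only decides whether those slots join the branch vector.
branch_forward <- function(Z_list, U_tgt, br, include_target = TRUE,
                           keep_cache = FALSE) {
  ens_in <- c(Z_list, list(U_tgt))
  E <- bind_groups(ens_in)
  fus <- mhsa_forward(E, br$attn, br$scale)
  m_out <- if (include_target) br$m else br$m - dim(U_tgt)[2L]
  kept <- fus$out[, seq_len(m_out), , drop = FALSE]
  vec <- flatten_groups(array(kept, c(dim(E)[1L], m_out, br$s)))
  cache <- if (keep_cache) {
    list(E = E, attn = fus$cache, m_out = m_out,
         sizes = vapply(ens_in, function(a) dim(a)[2L], 0L))
  } else {
    NULL
  }
  list(vec = vec, A = lapply(fus$cache$heads, `[[`, "A"), cache = cache)
}

branch_backward <- function(dvec, cache, br) {
  dKept <- unflatten_groups(dvec, cache$m_out, br$s)
  dF <- array(0, c(nrow(dvec), br$m, br$s))
  dF[, seq_len(cache$m_out), ] <- dKept
  bk <- mhsa_backward(dF, cache$attn, br$attn)
  # split dE back into the per-input arrays
  parts <- vector("list", length(cache$sizes))
  at <- 0L
  for (i in seq_along(cache$sizes)) {
    kk <- cache$sizes[i]
    d <- dim(bk$dU)
    part <- array(0, c(d[1L], kk, d[3L]))
    for (g in seq_len(kk)) part <- set_slab(part, g, slab(bk$dU, at + g))
    parts[[i]] <- part
    at <- at + kk
  }
  list(dparts = parts, grads = bk$grads)
}

#' Fuse the cross-modal embeddings of one target modality into a branch vector
#'
#' All cross-modal embeddings sharing the target modality `j`, together with
#' the target's own encoding `U^j`, form an ensemble of group vectors;
#' multi-head self-attention over the ensemble enriches the representation,
#' and the resulting vectors are concatenated into a single branch vector.
#'
#' @param cross_embeddings Non-empty list of `cross_modal_embedding`s, all
#'   with target `j`, in graph-config edge order.
#' @param U_target `encoded_modality` (or k_j x s_j matrix) of the target.
#' @param branch_params A [branch_init()] parameter set sized for the
#'   ensemble.
#' @param include_target Concatenate the target's own slots into the branch
#'   vector (default TRUE)?
#'
#' @return Numeric branch vector of length `m * s_j` where `m` is the
#'   ensemble size.
#' @export
fuse_target_branch <- function(cross_embeddings, U_target, branch_params,
                               include_target = TRUE) {
  if (length(cross_embeddings) == 0L) abort_("need at least one cross embedding")
  tgt <- unique(vapply(cross_embeddings, function(z) z$edge[2L], ""))
  if (length(tgt) != 1L) {
    abort_("mixed targets in cross_embeddings: ", paste(tgt, collapse = ", "))
  }
  Ut <- if (inherits(U_target, "encoded_modality")) U_target$U else U_target
  to_arr <- function(M) {
    a <- array(0, c(1L, nrow(M), ncol(M))); a[1L, , ] <- M; a
  }
  Z_list <- lapply(cross_embeddings, function(z) to_arr(z$Z))
  fw <- branch_forward(Z_list, to_arr(Ut), branch_params,
                       include_target = include_target)
  as.numeric(fw$vec[1L, ])
}

# ---- full model ----

#' Assemble a graph-guided cross-attention fusion model
#'
#' Builds the multimodal part of the architecture on top of (typically
#' phase-1-trained) modality encoders: one cross-attention module per graph
#' edge, one MHSA-enriched fusion branch per distinct edge target, unimodal
#' branches for zero-in-degree modalities, and a fully connected classifier.
#' Branch order is fixed: edge targets in order of first appearance in the
#' graph config, then zero-in-degree modalities in node order.
#'
#' @param encoders Named list of [encoder_init()] objects, one per graph node.
#' @param graph A [modality_graph()]; its nodes must all have encoders.
#' @param class_names Character vector of class names (length C).
#' @param cross_heads Heads per cross-attention module.
#' @param fusion_heads Heads of each branch's ensemble MHSA.
#' @param predictor_hidden Integer vector of predictor hidden-layer widths.
#' @param include_target_in_branch Include the target modality's own slots in
#'   each branch vector (default TRUE)?
#' @param scale Cross-attention logit scaling, see [cross_attention_init()].
#' @param layernorm Layer-normalize cross-attention inputs (default TRUE)?
#' @param seed Integer seed for weight initialization.
#'
#' @return An object of class `fuseomics_model`.
#' @export
build_model <- function(encoders, graph, class_names, cross_heads = 2L,
                        fusion_heads = 2L, predictor_hidden = 64L,
                        include_target_in_branch = TRUE,
                        scale = "sj", layernorm = TRUE, seed = 1L) {
  missing_enc <- setdiff(graph$nodes, names(encoders))
  if (length(missing_enc) > 0L) {
    abort_("no encoder for graph node(s): ", paste(missing_enc, collapse = ", "))
  }
  ebt <- edges_by_target(graph)
  uni <- zero_indegree(graph)
  branch_order <- c(names(ebt), uni)
  C <- length(class_names)

  with_seed_(seed, {
    edge_names <- vapply(graph$edges, paste, "", collapse = "->")
    edges <- list()
    for (i in seq_along(graph$edges)) {
      e <- graph$edges[[i]]
      edges[[edge_names[i]]] <- cross_attention_init(
        s_src = encoders[[e[1L]]]$s, s_tgt = encoders[[e[2L]]]$s,
        heads = cross_heads, scale = scale, layernorm = layernorm,
        seed = sample.int(.Machine$integer.max, 1L), edge = e
      )
    }
    branches <- list()
    for (tgt in names(ebt)) {
      # ensemble size: one k_j-group block per incoming edge plus the
      # target's own groups (always part of the MHSA ensemble)
      m_groups <- (length(ebt[[tgt]]) + 1L) * encoders[[tgt]]$partition$k
      branches[[tgt]] <- with_seed_(
        sample.int(.Machine$integer.max, 1L),
        branch_init(encoders[[tgt]]$s, fusion_heads, m_groups)
      )
    }
    dims <- vapply(branch_order, function(b) {
      if (b %in% names(ebt)) {
        m_out <- if (include_target_in_branch) {
          branches[[b]]$m
        } else {
          branches[[b]]$m - encoders[[b]]$partition$k
        }
        m_out * branches[[b]]$s
      } else {
        encoders[[b]]$partition$k * encoders[[b]]$s
      }
    }, 0L)
    predictor <- fcn_init(c(sum(dims), predictor_hidden, C))

    structure(list(
      graph = graph, encoders = encoders, edges = edges, branches = branches,
      predictor = predictor, class_names = class_names,
      branch_order = branch_order, branch_dims = dims,
      edges_by_target = ebt, unimodal_branches = uni,
      include_target_in_branch = include_target_in_branch,
      heads = list(), # phase-1 unimodal heads, filled by train_phase1
      config = list(cross_heads = cross_heads, fusion_heads = fusion_heads,
                    predictor_hidden = predictor_hidden, scale = scale,
                    layernorm = layernorm, seed = seed)
    ), class = "fuseomics_model")
  })
}

#' @export
print.fuseomics_model <- function(x, ...) {
  cat("<fuseomics_model> ", length(x$encoders), " encoders, ",
      length(x$edges), " cross-attention edges, ",
      length(x$class_names), " classes\n", sep = "")
  cat("  branches:", paste(x$branch_order, collapse = ", "), "\n")
  invisible(x)
}

# Encode every modality of a standardized dataset: named list of n x k x s.
encode_dataset <- function(model_or_encoders, dataset) {
  encoders <- if (inherits(model_or_encoders, "fuseomics_model")) {
    model_or_encoders$encoders
  } else {
    model_or_encoders
  }
  out <- list()
  for (nm in names(encoders)) {
    if (is.null(dataset$modalities[[nm]])) {
      abort_("dataset is missing modality '", nm, "'")
    }
    out[[nm]] <- encode_batch(dataset$modalities[[nm]]$values,
                              encoders[[nm]])$U
  }
  out
}

# Zero the encoded representation of masked/dropped modalities.
mask_encodings <- function(Ulist, missing) {
  for (nm in missing) {
    if (!nm %in% names(Ulist)) abort_("unknown modality to mask: '", nm, "'")
    Ulist[[nm]][] <- 0
  }
  Ulist
}

# Forward pass of the multimodal part over pre-encoded (and possibly masked)
# representations. Returns logits and, optionally, all caches for backprop.
multimodal_forward <- function(Ulist, model, keep_cache = FALSE) {
  ebt <- model$edges_by_target
  edge_caches <- list()
  Z_by_edge <- list()
  for (enm in names(model$edges)) {
    ca <- model$edges[[enm]]
    fw <- cross_attend_batch(Ulist[[ca$edge[1L]]], Ulist[[ca$edge[2L]]], ca,
                             keep_cache = keep_cache)
    Z_by_edge[[enm]] <- fw$Z
    if (keep_cache) edge_caches[[enm]] <- fw$cache
  }
  branch_caches <- list()
  vecs <- list()
  branch_attn <- list()
  for (b in model$branch_order) {
    if (b %in% names(ebt)) {
      enms <- paste(ebt[[b]], b, sep = "->")
      bf <- branch_forward(Z_by_edge[enms], Ulist[[b]], model$branches[[b]],
                           include_target = model$include_target_in_branch,
                           keep_cache = keep_cache)
      vecs[[b]] <- bf$vec
      branch_attn[[b]] <- bf$A
      if (keep_cache) branch_caches[[b]] <- bf$cache
    } else {
      vecs[[b]] <- flatten_groups(Ulist[[b]])
    }
  }
  Zvec <- do.call(cbind, vecs[model$branch_order])
  pf <- fcn_forward(Zvec, model$predictor, final_relu = FALSE)
  list(logits = pf$out, Z = Zvec, vecs = vecs, Z_by_edge = Z_by_edge,
       branch_attn = branch_attn,
       cache = if (keep_cache) {
         list(edges = edge_caches, branches = branch_caches,
              predictor = pf$cache)
       } else {
         NULL
       })
}

# Gradients of all multimodal (phase-2 trainable) parameters.
multimodal_backward <- function(dlogits, fw, model) {
  pb <- fcn_backward(dlogits, fw$cache$predictor, model$predictor)
  dZ <- pb$dX
  ebt <- model$edges_by_target
  offsets <- c(0L, cumsum(model$branch_dims))
  grads <- list(edges = list(), branches = list(), predictor = pb$grads)
  dZ_by_edge <- list()
  for (i in seq_along(model$branch_order)) {
    b <- model$branch_order[i]
    dvec <- dZ[, (offsets[i] + 1L):offsets[i + 1L], drop = FALSE]
    if (b %in% names(ebt)) {
      bb <- branch_backward(dvec, fw$cache$branches[[b]], model$branches[[b]])
      grads$branches[[b]] <- bb$grads
      enms <- paste(ebt[[b]], b, sep = "->")
      for (j in seq_along(enms)) dZ_by_edge[[enms[j]]] <- bb$dparts[[j]]
      # bb$dparts[[length(enms)+1]] is the target-encoding slot; encoders are
      # frozen in phase 2 so that gradient is discarded.
    }
  }
  for (enm in names(model$edges)) {
    eb <- cross_attend_backward(dZ_by_edge[[enm]], fw$cache$edges[[enm]],
                                model$edges[[enm]])
    grads$edges[[enm]] <- eb$grads
  }
  grads
}

# Extract / replace the phase-2 trainable parameter tree.
mm_params <- function(model) {
  list(edges = lapply(model$edges, `[[`, "params"),
       branches = lapply(model$branches, `[[`, "attn"),
       predictor = model$predictor)
}

set_mm_params <- function(model, params) {
  for (enm in names(model$edges)) model$edges[[enm]]$params <- params$edges[[enm]]
  for (b in names(model$branches)) model$branches[[b]]$attn <- params$branches[[b]]
  model$predictor <- params$predictor
  model
}

# Align a gradient tree with the mm_params() layout.
mm_grads_tree <- function(grads, model) {
  list(edges = grads$edges[names(model$edges)],
       branches = lapply(names(model$branches), function(b) grads$branches[[b]]) |>
         stats::setNames(names(model$branches)),
       predictor = grads$predictor)
}

#' Full forward pass for one multimodal sample
#'
#' Deterministic composition encode -> cross-attend per edge -> fuse per
#' target branch -> classify.
#'
#' @param model A trained (or initialized) `fuseomics_model`.
#' @param x Named list of numeric feature vectors, one per modality, on the
#'   standardized scale used in training.
#' @param missing Character vector of modalities to mask (their encoded
#'   representation is zeroed, as in modality dropout); must leave at least
#'   one modality present.
#'
#' @return An object of class `fused_representation`: list with
#'   `branch_vectors` (named list), `Z` (concatenated multimodal vector),
#'   `logits` and `probabilities` (length C, sums to 1).
#' @export
forward_pass <- function(model, x, missing = character()) {
  need <- setdiff(names(model$encoders), missing)
  absent <- setdiff(need, names(x))
  if (length(absent) > 0L) {
    abort_("modality '", paste(absent, collapse = "', '"),
           "' missing without a mask directive")
  }
  if (length(setdiff(names(model$encoders), missing)) == 0L) {
    abort_("all modalities masked; at least one must be present")
  }
  Ulist <- list()
  for (nm in names(model$encoders)) {
    Ulist[[nm]] <- if (nm %in% missing) {
      array(0, c(1L, model$encoders[[nm]]$partition$k, model$encoders[[nm]]$s))
    } else {
      encode_batch(matrix(as.numeric(x[[nm]]), nrow = 1L),
                   model$encoders[[nm]])$U
    }
  }
  fw <- multimodal_forward(Ulist, model)
  probs <- softmax_rows(fw$logits)
  structure(list(
    branch_vectors = lapply(fw$vecs, function(v) as.numeric(v[1L, ])),
    Z = as.numeric(fw$Z[1L, ]),
    logits = stats::setNames(as.numeric(fw$logits[1L, ]), model$class_names),
    probabilities = stats::setNames(as.numeric(probs[1L, ]), model$class_names)
  ), class = "fused_representation")
}

#' Predict class probabilities for a multiomics dataset
#'
#' @param object A trained `fuseomics_model`.
#' @param dataset A standardized `multiomics_dataset` containing every
#'   modality the model was built for.
#' @param missing Character vector of modalities to mask at the encoded level.
#' @param ... Unused.
#'
#' @return A tibble with `sample_id`, `predicted_class`, and one probability
#'   column per class (`p_<class>`).
#' @export
predict.fuseomics_model <- function(object, dataset, missing = character(), ...) {
  if (length(setdiff(names(object$encoders), missing)) == 0L) {
    abort_("all modalities masked; at least one must be present")
  }
  Ulist <- mask_encodings(encode_dataset(object, dataset), missing)
  fw <- multimodal_forward(Ulist, object)
  probs <- softmax_rows(fw$logits)
  colnames(probs) <- paste0("p_", object$class_names)
  pred <- object$class_names[max.col(probs, ties.method = "first")]
  dplyr::bind_cols(
    tibble::tibble(sample_id = sample_ids(dataset), predicted_class = pred),
    tibble::as_tibble(probs)
  )
}
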