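# Layer-wise relevance propagation (epsilon rule) through the trained model.
#
# Affine layers use the epsilon rule; attention mixing is treated as fixed
# coefficients (relevance distributed proportionally to the A * value
# contributions); residual connections split relevance proportionally to each
# summand; layer normalization is treated as a fixed per-coordinate scaling
# (the relevance of y_d flows to x_d in proportion (y_d - beta_d) / y_d, the
# mean/variance treated as constants). ReLU passes relevance through
# unchanged. Relevance absorbed by bias terms is tracked and reported.

# epsilon rule through one affine map z = x %*% W + b, vectors x, z, R.
lrp_affine_vec <- function(x, W, b, z, R, eps) {
  s <- R / (z + eps * sign0(z))
  list(R_in = as.numeric(x) * as.numeric(W %*% s),
       R_bias = sum(as.numeric(b) * s))
}

# Relevance through fixed-coefficient attention mixing out = A %*% V.
# A: kq x kk (row-stochastic), V: kk x l, R_out: kq x l -> R_V: kk x l.
lrp_attention_mix <- function(A, V, R_out, eps) {
  out <- A %*% V
  S <- R_out / (out + eps * sign0(out))
  V * (t(A) %*% S)
}

#' Epsilon-rule LRP through a fully connected stack
#'
#' Runs the stack forward on `x` and back-propagates the output relevance
#' `R_out` through every affine layer with the epsilon rule (ReLU layers pass
#' relevance through unchanged).
#'
#' @param layers FCN parameters: list per layer of `list(W, b)` with `W`
#'   d_in x d_out.
#' @param x Numeric input vector.
#' @param R_out Numeric relevance vector at the output layer.
#' @param eps Epsilon stabilizer.
#' @param final_relu Does the last layer apply ReLU?
#' @return List with `R_in` (relevance per input), `R_bias` (total relevance
#'   absorbed by bias terms) and `out` (the forward output).
#' @export
lrp_fcn <- function(layers, x, R_out, eps = 1e-6, final_relu = TRUE) {
  fw <- fcn_forward(matrix(as.numeric(x), 1L), layers, final_relu = final_relu)
  R <- as.numeric(R_out)
  bias_total <- 0
  for (i in rev(seq_along(layers))) {
    xi <- as.numeric(fw$cache$acts[[i]])
    zi <- as.numeric(fw$cache$pre[[i]])
    st <- lrp_affine_vec(xi, layers[[i]]$W, layers[[i]]$b, zi, R, eps)
    R <- st$R_in
    bias_total <- bias_total + st$R_bias
  }
  list(R_in = R, R_bias = bias_total, out = as.numeric(fw$out))
}

# n=1 array -> matrix
m1 <- function(A3) matrix(A3[1L, , ], dim(A3)[2L], dim(A3)[3L])

# Relevance through single-sample MHSA (concatenated heads, no projection):
# R_out on the k x s output -> R on the k x s input E, using cached Q/K/V/A.
lrp_mhsa_single <- function(E, head_caches, head_params, R_out, eps) {
  k <- nrow(E); s <- ncol(E)
  H <- length(head_params)
  l <- s %/% H
  R_E <- matrix(0, k, s)
  for (h in seq_len(H)) {
    hc <- head_caches[[h]]
    A <- m1(hc$A); V <- m1(hc$V)
    cols <- ((h - 1L) * l + 1L):(h * l)
    R_V <- lrp_attention_mix(A, V, R_out[, cols, drop = FALSE], eps)
    Wv <- head_params[[h]]$Wv
    for (q in seq_len(nrow(V))) {
      st <- lrp_affine_vec(E[q, ], Wv, numeric(l), V[q, ], R_V[q, ], eps)
      R_E[q, ] <- R_E[q, ] + st$R_in
    }
  }
  R_E
}

# As above but for cross-attention: queries/keys carry no relevance; values
# come from the (normalized) source. Returns relevance on the source input.
lrp_cross_values <- function(Us_norm, head_caches, head_params, R_out, eps) {
  ki <- nrow(Us_norm)
  s_src <- ncol(Us_norm)
  H <- length(head_params)
  l <- ncol(R_out) %/% H
  R_src <- matrix(0, ki, s_src)
  for (h in seq_len(H)) {
    hc <- head_caches[[h]]
    A <- m1(hc$A); V <- m1(hc$V)
    cols <- ((h - 1L) * l + 1L):(h * l)
    R_V <- lrp_attention_mix(A, V, R_out[, cols, drop = FALSE], eps)
    Wv <- head_params[[h]]$Wv
    for (q in seq_len(ki)) {
      st <- lrp_affine_vec(Us_norm[q, ], Wv, numeric(l), V[q, ], R_V[q, ], eps)
      R_src[q, ] <- R_src[q, ] + st$R_in
    }
  }
  R_src
}

# Relevance through layer normalization, coefficients treated as constants:
# R_x,d = (y_d - beta_d) / (y_d + eps) * R_y,d, row-wise over groups.
lrp_layernorm <- function(Y, beta, R_Y, eps) {
  contrib <- sweep(Y, 2L, beta, "-")
  contrib / (Y + eps * sign0(Y)) * R_Y
}

#' Layer-wise relevance propagation through a trained model
#'
#' Back-propagates the pre-softmax score of `target_class` (or, with
#' `seed_from_probability = TRUE`, the literal predicted probability) through
#' the predictor, the fusion branches, the cross-attention modules and the
#' encoders, assigning a relevance score to every neuron. All modalities must
#' be present (masked-modality attribution is excluded).
#'
#' @param model A trained `fuseomics_model`.
#' @param x Named list of standardized feature vectors, one per modality.
#' @param target_class Class name or index whose prediction signal is
#'   decomposed.
#' @param epsilon Epsilon stabilizer of the LRP rule (default 1e-6).
#' @param seed_from_probability Seed relevance from the softmax probability
#'   instead of the pre-softmax logit (the logit avoids softmax cross-talk).
#'
#' @return List of class `lrp_relevance` with per-layer relevance maps:
#'   `logits` (length C), `multimodal` (the fused vector), `branches`,
#'   `ensemble_slots` (relevance arriving at each edge's slots of the fusion
#'   ensemble), `edges` (named list of k_j x s_j matrices: the relevance
#'   attributed to each edge's cross-attention output at the residual split —
#'   a zero-contribution edge scores exactly zero), `edge_means` (named
#'   numeric), `U` (per modality k x s),
#'   `input` (per modality length-p vectors), `bias_absorbed`, `epsilon`,
#'   `rule`, and `diagnostics` (tibble of relevance totals per stage).
#' @export
lrp_relevance <- function(model, x, target_class, epsilon = 1e-6,
                          seed_from_probability = FALSE) {
  mods <- names(model$encoders)
  absent <- setdiff(mods, names(x))
  if (length(absent) > 0L) {
    abort_("LRP requires all modalities present; missing: ",
           paste(absent, collapse = ", "))
  }
  if (is.character(target_class)) {
    c_idx <- match(target_class, model$class_names)
    if (is.na(c_idx)) abort_("unknown class '", target_class, "'")
  } else {
    c_idx <- as.integer(target_class)
    if (c_idx < 1L || c_idx > length(model$class_names)) {
      abort_("target_class index out of range")
    }
  }

  # forward with caches (n = 1 batch path, same code as training/inference)
  Ulist <- list(); enc_caches <- list()
  for (nm in mods) {
    fw <- encode_batch(matrix(as.numeric(x[[nm]]), 1L),
                       model$encoders[[nm]], keep_cache = TRUE)
    Ulist[[nm]] <- fw$U
    enc_caches[[nm]] <- fw$cache
  }
  fw <- multimodal_forward(Ulist, model, keep_cache = TRUE)
  logits <- as.numeric(fw$logits[1L, ])
  probs <- as.numeric(softmax_rows(fw$logits)[1L, ])
  seed_val <- if (seed_from_probability) probs[c_idx] else logits[c_idx]

  R_logits <- numeric(length(logits))
  R_logits[c_idx] <- seed_val
  bias_absorbed <- 0

  # predictor FCN (final layer has no ReLU)
  pc <- fw$cache$predictor
  R <- R_logits
  for (i in rev(seq_along(model$predictor))) {
    st <- lrp_affine_vec(as.numeric(pc$acts[[i]]),
                         model$predictor[[i]]$W, model$predictor[[i]]$b,
                         as.numeric(pc$pre[[i]]), R, epsilon)
    R <- st$R_in
    bias_absorbed <- bias_absorbed + st$R_bias
  }
  R_Z <- R
  fcn_input_relevance <- sum(R_Z)

  # split the multimodal vector into branches
  offsets <- c(0L, cumsum(model$branch_dims))
  ebt <- model$edges_by_target
  R_branches <- list()
  R_edges <- list()
  R_U <- lapply(Ulist, function(U) matrix(0, dim(U)[2L], dim(U)[3L]))
  for (i in seq_along(model$branch_order)) {
    b <- model$branch_order[i]
    Rv <- R_Z[(offsets[i] + 1L):offsets[i + 1L]]
    R_branches[[b]] <- Rv
    if (b %in% names(ebt)) {
      br <- model$branches[[b]]
      bc <- fw$cache$branches[[b]]
      R_kept <- matrix(0, br$m, br$s)
      R_kept[seq_len(bc$m_out), ] <- matrix(Rv, bc$m_out, br$s, byrow = TRUE)
      E <- m1(bc$E)
      R_E <- lrp_mhsa_single(E, bc$attn$heads, br$attn$heads, R_kept, epsilon)
      # split the ensemble: one k_j block per incoming edge, then the target
      at <- 0L
      for (src in ebt[[b]]) {
        kk <- bc$sizes[match(src, ebt[[b]])]
        enm <- paste(src, b, sep = "->")
        R_edges[[enm]] <- R_E[(at + 1L):(at + kk), , drop = FALSE]
        at <- at + kk
      }
      R_U[[b]] <- R_U[[b]] + R_E[(at + 1L):nrow(R_E), , drop = FALSE]
    } else {
      R_U[[b]] <- R_U[[b]] +
        matrix(Rv, dim(Ulist[[b]])[2L], dim(Ulist[[b]])[3L], byrow = TRUE)
    }
  }

  # through each cross-attention module: residual split, W^O, value path.
  # The edge importance is the relevance attributed to the cross-attention
  # output proper (the W^O-fused head output) at the residual split, so a
  # dead edge (zero contribution) scores exactly zero instead of inheriting
  # the relevance the residual merely passes through.
  R_edge_attn <- list()
  for (enm in names(model$edges)) {
    ca <- model$edges[[enm]]
    cc <- fw$cache$edges[[enm]]
    R_Ze <- R_edges[[enm]]
    CAout <- m1(cc$CAout); U_tgt <- m1(cc$U_tgt)
    Zmat <- CAout + U_tgt
    denom <- Zmat + epsilon * sign0(Zmat)
    R_CA <- CAout / denom * R_Ze
    R_res <- U_tgt / denom * R_Ze
    R_edge_attn[[enm]] <- R_CA
    R_U[[ca$edge[2L]]] <- R_U[[ca$edge[2L]]] + R_res
    O <- m1(cc$O)
    R_O <- matrix(0, nrow(O), ncol(O))
    for (p in seq_len(nrow(O))) {
      st <- lrp_affine_vec(O[p, ], ca$params$Wo, numeric(ncol(O)),
                           CAout[p, ], R_CA[p, ], epsilon)
      R_O[p, ] <- st$R_in
    }
    Us_norm <- m1(cc$Us)
    R_src_norm <- lrp_cross_values(Us_norm, cc$heads, ca$params$heads,
                                   R_O, epsilon)
    if (ca$layernorm) {
      R_src <- lrp_layernorm(Us_norm, ca$params$ln_src$beta, R_src_norm,
                             epsilon)
    } else {
      R_src <- R_src_norm
    }
    R_U[[ca$edge[1L]]] <- R_U[[ca$edge[1L]]] + R_src
  }
  edge_means <- vapply(R_edge_attn, mean, 0)

  # through each encoder: MHSA value path, then per-group FCNs to the input
  R_input <- list()
  for (nm in mods) {
    enc <- model$encoders[[nm]]
    ec <- enc_caches[[nm]]
    U0 <- m1(ec$attn$U)
    R_U0 <- lrp_mhsa_single(U0, ec$attn$heads, enc$params$attn$heads,
                            R_U[[nm]], epsilon)
    R_feat <- numeric(enc$partition$p)
    for (g in seq_len(enc$partition$k)) {
      idx <- enc$partition$assignment[[g]]
      st <- lrp_fcn(enc$params$fcn[[g]], as.numeric(x[[nm]])[idx],
                    R_U0[g, ], eps = epsilon, final_relu = TRUE)
      R_feat[idx] <- st$R_in
      bias_absorbed <- bias_absorbed + st$R_bias
    }
    if (!all(is.finite(R_feat))) {
      abort_("non-finite relevance in encoder '", nm, "'")
    }
    R_input[[nm]] <- R_feat
  }

  diagnostics <- tibble::tibble(
    stage = c("logit_seed", "multimodal_vector", "encoded_U", "input"),
    total_relevance = c(seed_val, sum(R_Z),
                        sum(vapply(R_U, sum, 0)),
                        sum(vapply(R_input, sum, 0)))
  )
  structure(list(
    target_class = model$class_names[c_idx],
    logits = stats::setNames(logits, model$class_names),
    relevance_logits = stats::setNames(R_logits, model$class_names),
    multimodal = R_Z, branches = R_branches, ensemble_slots = R_edges,
    edges = R_edge_attn, edge_means = edge_means, U = R_U, input = R_input,
    bias_absorbed = bias_absorbed, epsilon = epsilon, rule = "epsilon",
    fcn_input_relevance = fcn_input_relevance,
    diagnostics = diagnostics
  ), class = "lrp_relevance")
}

#' Per-edge interaction importance from LRP
#'
#' For every sample, the importance of an interaction edge (i -> j) is the
#' mean LRP relevance over the output neurons of its cross-modal embedding
#' Z^(i->j). Class-level scores average the per-sample scores within each
#' class (true labels by default).
#'
#' @param model A trained `fuseomics_model`.
#' @param dataset A standardized `multiomics_dataset` with all modalities.
#' @param class_filter Optional character vector restricting to some classes.
#' @param use_predicted Aggregate by (and seed relevance at) the predicted
#'   class instead of the true label?
#' @param epsilon Epsilon stabilizer.
#' @param signed Report the raw signed mean relevance per edge instead of
#'   the mean magnitude? Relevance is a signed decomposition (evidence for
#'   and against the class score), and over an edge's output neurons the two
#'   signs largely cancel; the mean magnitude is the meaningful measure of
#'   how much relevance flows through an interaction, so it is the default.
#' @param normalize Normalize each class's edge scores to sum to 1?
#'
#' @return Object of class `relevance_report`: list with `samples` (tibble:
#'   sample_id, class, edge, relevance), `class_means` (tibble: class, edge,
#'   mean_relevance, n_samples), `cohort` (tibble: edge, mean_relevance),
#'   `rule`, `epsilon`, `by`, `normalized`.
#' @export
interaction_importance <- function(model, dataset, class_filter = NULL,
                                   use_predicted = FALSE, epsilon = 1e-6,
                                   signed = FALSE, normalize = FALSE) {
  if (n_samples(dataset) == 0L) abort_("empty dataset")
  if (length(model$edges) == 0L) abort_("model has no interaction edges")
  ids <- sample_ids(dataset)
  truth <- as.character(dataset$labels)
  pred_cls <- if (use_predicted) {
    predict(model, dataset)$predicted_class
  } else {
    truth
  }
  keep <- if (is.null(class_filter)) {
    rep(TRUE, length(ids))
  } else {
    pred_cls %in% class_filter
  }
  if (!any(keep)) abort_("no samples left after class filtering")
  rows <- list()
  for (i in which(keep)) {
    xi <- lapply(dataset$modalities, function(m) m$values[i, ])
    rel <- lrp_relevance(model, xi, pred_cls[i], epsilon = epsilon)
    score <- if (signed) {
      rel$edge_means
    } else {
      vapply(rel$edges, function(R) mean(abs(R)), 0)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = ids[i], class = pred_cls[i],
      edge = names(score), relevance = as.numeric(score))
  }
  samples <- dplyr::bind_rows(rows)
  class_means <- samples |>
    dplyr::group_by(.data$class, .data$edge) |>
    dplyr::summarise(mean_relevance = mean(.data$relevance),
                     n_samples = dplyr::n(), .groups = "drop")
  if (normalize) {
    class_means <- class_means |>
      dplyr::group_by(.data$class) |>
      dplyr::mutate(mean_relevance = .data$mean_relevance /
                      sum(abs(.data$mean_relevance))) |>
      dplyr::ungroup()
  }
  cohort <- samples |>
    dplyr::group_by(.data$edge) |>
    dplyr::summarise(mean_relevance = mean(.data$relevance), .groups = "drop")
  structure(list(samples = samples, class_means = class_means,
                 cohort = cohort, rule = "epsilon", epsilon = epsilon,
                 by = if (use_predicted) "predicted" else "label",
                 signed = signed, normalized = normalize),
            class = "relevance_report")
}

#' @export
print.relevance_report <- function(x, ...) {
  cat("<relevance_report> rule = ", x$rule, " (epsilon = ", x$epsilon,
      "), aggregated by ", x$by, "\n", sep = "")
  print(x$class_means)
  invisible(x)
}
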