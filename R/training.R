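#' Inverse-frequency class weights for the weighted cross-entropy loss
#'
#' Weights are proportional to the inverse class size and normalized so their
#' mean under the class distribution is one: `w_c = n / (C * n_c)`. With
#' balanced classes every weight is exactly 1 and the loss reduces to the
#' unweighted cross-entropy.
#'
#' @param labels Factor of class labels (every declared level must appear).
#' @return Named numeric vector of length C.
#' @export
class_weights <- function(labels) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts == 0L)) {
    abort_("empty class(es): ",
           paste(names(counts)[counts == 0L], collapse = ", "))
  }
  n <- length(labels)
  C <- length(counts)
  w <- n / (C * as.numeric(counts))
  stats::setNames(w, names(counts))
}

# Weighted cross-entropy on logits. y: integer class in 1..C, w: length C.
# Returns mean over the batch of w[y] * (-log p[y]) and the logit gradient.
# With smooth > 0, targets are label-smoothed: (1 - smooth) on the true class
# and smooth / C everywhere, which keeps the validation loss calibrated (and
# therefore usable for early stopping) instead of rewarding overconfidence.
weighted_ce <- function(logits, y, w, smooth = 0) {
  P <- softmax_rows(logits)
  n <- nrow(logits)
  C <- ncol(logits)
  idx <- cbind(seq_len(n), y)
  wy <- w[y]
  logP <- log(pmax(P, 1e-12))
  if (smooth > 0) {
    Tm <- matrix(smooth / C, n, C)
    Tm[idx] <- Tm[idx] + (1 - smooth)
  } else {
    Tm <- matrix(0, n, C)
    Tm[idx] <- 1
  }
  loss <- mean(wy * -rowSums(Tm * logP))
  dlogits <- (P - Tm) * (wy / n)
  list(loss = loss, dlogits = dlogits)
}

# ---- Adam over parameter trees ----

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  if (weight_decay > 0) {
    # decoupled weight decay (AdamW); bias/gain vectors are decayed too,
    # which is harmless at these scales
    params <- tree_map(function(p) p * (1 - lr * weight_decay), params)
  }
  list(params = params, state = state)
}

make_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' Phase 1: train each modality encoder individually
#'
#' Every encoder is trained end-to-end with its own unimodal softmax head on
#' the weighted cross-entropy loss; the parameters with the best validation
#' loss are kept. Heads are retained (for unimodal baselines) alongside the
#' encoders.
#'
#' @param train,val Standardized `multiomics_dataset`s.
#' @param encoder_configs Named list per modality: list with `k`, `s`,
#'   `heads`, optional `fcn_hidden`, optional `partition_seed`. A single
#'   unnamed list is recycled to every modality.
#' @param seed Integer training seed (initialization + batch order).
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param weight_decay Decoupled (AdamW-style) weight decay.
#' @param label_smoothing Label-smoothing mass in `[0, 1)`.
#' @param patience Early-stopping patience on validation loss (epochs).
#' @param verbose Print a line per epoch?
#'
#' @return List with `encoders` (named list, best-validation weights),
#'   `heads` (named list of unimodal heads), and `history` (tibble with
#'   modality, epoch, train_loss, val_loss, val_accuracy).
#' @export
train_phase1 <- function(train, val, encoder_configs = list(), seed = 1L,
                         epochs = 40L, batch_size = 32L, lr = 1e-3,
                         weight_decay = 0, label_smoothing = 0,
                         patience = 20L, verbose = FALSE) {
  mods <- modality_names(train)
  if (is.null(names(encoder_configs)) && length(encoder_configs) > 0L &&
      !is.list(encoder_configs[[1L]])) {
    encoder_configs <- stats::setNames(rep(list(encoder_configs), length(mods)),
                                       mods)
  }
  C <- length(train$class_names)
  w <- class_weights(train$labels)
  y_tr <- as.integer(train$labels)
  y_va <- as.integer(val$labels)
  encoders <- list(); heads <- list()
  hist <- list()

  for (nm in mods) {
    cfg <- encoder_configs[[nm]] %||% list()
    k <- cfg$k %||% 4L
    s <- cfg$s %||% 16L
    H <- cfg$heads %||% 2L
    p <- length(train$modalities[[nm]]$feature_ids)
    part <- make_partition(p, k, seed = cfg$partition_seed %||% (seed + 1000L),
                           modality_name = nm)
    enc <- encoder_init(part, s = s, heads = H, fcn_hidden = cfg$fcn_hidden,
                        seed = seed)
    head <- with_seed_(seed + 1L, unimodal_head_init(k, s, C))
    Xtr <- train$modalities[[nm]]$values
    Xva <- val$modalities[[nm]]$values

    params <- list(enc = enc$params, head = head)
    opt <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L

    run <- with_seed_(seed + 2L, {
      for (ep in seq_len(epochs)) {
        ep_loss <- 0; nb <- 0L
        for (b in make_batches(nrow(Xtr), batch_size)) {
          enc$params <- params$enc
          fw <- encode_batch(Xtr[b, , drop = FALSE], enc, keep_cache = TRUE)
          logits <- head_logits_batch(fw$U, params$head)
          ce <- weighted_ce(logits, y_tr[b], w, smooth = label_smoothing)
          if (!is.finite(ce$loss)) {
            abort_("phase 1 diverged (non-finite loss) for modality '", nm,
                   "' at epoch ", ep)
          }
          d <- dim(fw$U)
          dUflat <- ce$dlogits %*% t(params$head$W)
          dU <- array(dUflat, d)
          g_enc <- encoder_backward(dU, fw$cache, enc)
          Uflat <- matrix(fw$U, d[1L], d[2L] * d[3L])
          g_head <- list(W = crossprod(Uflat, ce$dlogits),
                         b = colSums(ce$dlogits))
          st <- adam_step(params, list(enc = g_enc, head = g_head), opt, lr,
                          weight_decay = weight_decay)
          params <- st$params; opt <- st$state
          ep_loss <- ep_loss + ce$loss; nb <- nb + 1L
        }
        enc$params <- params$enc
        fv <- encode_batch(Xva, enc)
        vl <- head_logits_batch(fv$U, params$head)
        vce <- weighted_ce(vl, y_va, w, smooth = label_smoothing)
        vacc <- mean(max.col(vl, ties.method = "first") == y_va)
        hist[[length(hist) + 1L]] <- tibble::tibble(
          modality = nm, epoch = ep, train_loss = ep_loss / nb,
          val_loss = vce$loss, val_accuracy = vacc)
        if (verbose) {
          message(sprintf("[phase1 %s] epoch %d train %.4f val %.4f acc %.3f",
                          nm, ep, ep_loss / nb, vce$loss, vacc))
        }
        if (vce$loss < best$loss - 1e-9) {
          best <- list(loss = vce$loss, params = params, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      }
      best
    })
    enc$params <- run$params$enc
    encoders[[nm]] <- enc
    heads[[nm]] <- run$params$head
  }
  list(encoders = encoders, heads = heads,
       history = if (length(hist)) dplyr::bind_rows(hist) else tibble::tibble())
}

#' Phase 2: train the multimodal weights on frozen encoders
#'
#' Encoders are frozen (their parameters are bit-identical before and after,
#' asserted via checksum) and every sample's encoded representation is cached
#' once; only the cross-attention, fusion-branch and predictor weights are
#' updated, with the weighted cross-entropy loss. With `dropout_p > 0`, at
#' each iteration each modality is independently dropped with that
#' probability (encoded groups zeroed), re-keeping random dropped modalities
#' whenever more than `max_dropped` were drawn.
#'
#' @param train,val Standardized `multiomics_dataset`s.
#' @param model A [build_model()] object whose encoders are phase-1 trained.
#' @param seed Integer training seed.
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to the
#'   predictor and fusion-branch parameters.
#' @param label_smoothing Label-smoothing mass in `[0, 1)` spread uniformly
#'   over the classes; keeps the validation loss calibrated for early
#'   stopping.
#' @param attention_decay Decoupled weight decay for the cross-attention
#'   projections and layer norms (default 0: attention logits are free to
#'   move away from uniform).
#' @param patience Early-stopping patience on validation loss.
#' @param dropout_p Per-modality dropout probability P in `[0, 1]`.
#' @param max_dropped Cap on simultaneously dropped modalities (`< M`).
#' @param select Checkpoint selection: the epoch with the best validation
#'   accuracy (default; ties broken by lower loss) or the best validation
#'   loss. Early *stopping* always watches the validation loss.
#' @param lr_schedule `"constant"` (default) or `"cosine"` decay of the
#'   learning rate to zero across the epoch budget.
#' @param swa_start Epoch from which to also maintain a stochastic
#'   weight average of the multimodal parameters; the averaged model replaces
#'   the selected checkpoint only if it has higher validation accuracy.
#'   `0` (default) disables averaging.
#' @param verbose Print a line per epoch?
#'
#' @return List with `model` (best-validation multimodal weights), `history`
#'   tibble, and `freeze_check` (logical: encoder checksums unchanged).
#' @export
train_phase2 <- function(train, val, model, seed = 1L, epochs = 60L,
                         batch_size = 32L, lr = 1e-3, weight_decay = 0,
                         attention_decay = 0, label_smoothing = 0,
                         patience = 20L, dropout_p = 0,
                         max_dropped = 0L, select = c("accuracy", "loss"),
                         swa_start = 0L, lr_schedule = c("constant", "cosine"),
                         verbose = FALSE) {
  select <- match.arg(select)
  lr_schedule <- match.arg(lr_schedule)
  M <- length(model$encoders)
  if (max_dropped >= M) abort_("max_dropped must be < number of modalities")
  if (dropout_p < 0 || dropout_p > 1) abort_("dropout_p must be in [0, 1]")
  for (nm in names(model$encoders)) {
    if (is.null(train$modalities[[nm]])) {
      abort_("missing encoder input: train data has no modality '", nm, "'")
    }
  }
  w <- class_weights(train$labels)
  y_tr <- as.integer(train$labels)
  y_va <- as.integer(val$labels)
  ck_before <- params_checksum(lapply(model$encoders, `[[`, "params"))

  U_tr <- encode_dataset(model, train)
  U_va <- encode_dataset(model, val)
  mods <- names(model$encoders)

  params <- mm_params(model)
  opt <- adam_init(params)
  best <- list(loss = Inf, acc = -Inf, params = params, epoch = 0L)
  stop_best <- Inf
  wait <- 0L
  hist <- list()
  swa <- NULL; swa_n <- 0L

  subset_U <- function(Ulist, b) {
    lapply(Ulist, function(U) {
      array(U[b, , , drop = FALSE], c(length(b), dim(U)[2L], dim(U)[3L]))
    })
  }

  with_seed_(seed + 3L, {
    for (ep in seq_len(epochs)) {
      lr_ep <- if (lr_schedule == "cosine") {
        lr * 0.5 * (1 + cos(pi * (ep - 1) / max(1L, epochs)))
      } else {
        lr
      }
      ep_loss <- 0; nb <- 0L
      for (b in make_batches(length(y_tr), batch_size)) {
        model <- set_mm_params(model, params)
        Ub <- subset_U(U_tr, b)
        if (dropout_p > 0) {
          keep <- sample_dropout_mask(M, dropout_p, max_dropped)
          Ub <- mask_encodings(Ub, mods[!keep])
        }
        fw <- multimodal_forward(Ub, model, keep_cache = TRUE)
        ce <- weighted_ce(fw$logits, y_tr[b], w, smooth = label_smoothing)
        if (!is.finite(ce$loss)) {
          abort_("phase 2 diverged (non-finite loss) at epoch ", ep)
        }
        grads <- mm_grads_tree(multimodal_backward(ce$dlogits, fw, model), model)
        st <- adam_step(params, grads, opt, lr_ep)
        params <- st$params; opt <- st$state
        # decay the classifier side only: shrinking the attention projections
        # would pin the attention at uniform and disable interaction learning
        if (weight_decay > 0) {
          f <- function(p) p * (1 - lr_ep * weight_decay)
          params$predictor <- tree_map(f, params$predictor)
          params$branches <- tree_map(f, params$branches)
        }
        if (attention_decay > 0) {
          params$edges <- tree_map(function(p) p * (1 - lr_ep * attention_decay),
                                   params$edges)
        }
        ep_loss <- ep_loss + ce$loss; nb <- nb + 1L
      }
      if (swa_start > 0L && ep >= swa_start) {
        # running average of the post-update weights (stochastic weight
        # averaging); the averaged model competes with the best single epoch
        # on validation accuracy below
        swa_n <- swa_n + 1L
        swa <- if (is.null(swa)) params else {
          tree_map2(function(a, b) a + (b - a) / swa_n, swa, params)
        }
      }
      model <- set_mm_params(model, params)
      fv <- multimodal_forward(U_va, model)
      vce <- weighted_ce(fv$logits, y_va, w, smooth = label_smoothing)
      vacc <- mean(max.col(fv$logits, ties.method = "first") == y_va)
      hist[[length(hist) + 1L]] <- tibble::tibble(
        modality = "multimodal", epoch = ep, train_loss = ep_loss / nb,
        val_loss = vce$loss, val_accuracy = vacc)
      if (verbose) {
        message(sprintf("[phase2] epoch %d train %.4f val %.4f acc %.3f",
                        ep, ep_loss / nb, vce$loss, vacc))
      }
      better <- if (select == "accuracy") {
        vacc > best$acc + 1e-12 || (vacc >= best$acc - 1e-12 &&
                                      vce$loss < best$loss - 1e-9)
      } else {
        vce$loss < best$loss - 1e-9
      }
      if (better) {
        best <- list(loss = vce$loss, acc = vacc, params = params, epoch = ep)
      }
      # early stopping is always on the validation loss
      if (vce$loss < stop_best - 1e-9) {
        stop_best <- vce$loss
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  if (!is.null(swa) && swa_n > 1L) {
    m_swa <- set_mm_params(model, swa)
    fv <- multimodal_forward(U_va, m_swa)
    acc_swa <- mean(max.col(fv$logits, ties.method = "first") == y_va)
    if (acc_swa > best$acc + 1e-12) {
      best$params <- swa
      best$acc <- acc_swa
    }
  }
  if (epochs > 0L) model <- set_mm_params(model, best$params)
  ck_after <- params_checksum(lapply(model$encoders, `[[`, "params"))
  freeze_ok <- identical(ck_before, ck_after)
  if (!freeze_ok) abort_("freeze invariant violated: encoder parameters changed")
  list(model = model,
       history = if (length(hist)) dplyr::bind_rows(hist) else tibble::tibble(),
       freeze_check = freeze_ok)
}

#' Sample a modality keep-mask for dropout training
#'
#' Each of the M modalities is independently dropped with probability `P`;
#' if more than `max_dropped` were drawn, uniformly chosen dropped modalities
#' are re-kept until the cap holds. Uses the current RNG stream.
#'
#' @param M Number of modalities.
#' @param P Drop probability in `[0, 1]`.
#' @param max_dropped Cap on dropped modalities, `0 <= max_dropped < M`.
#' @return Logical keep-mask of length M (`TRUE` = modality kept).
#' @export
sample_dropout_mask <- function(M, P, max_dropped) {
  if (P < 0 || P > 1) abort_("P must be in [0, 1]")
  if (max_dropped < 0L || max_dropped >= M) {
    abort_("max_dropped must satisfy 0 <= max_dropped < M")
  }
  drop <- stats::runif(M) < P
  excess <- sum(drop) - max_dropped
  if (excess > 0) {
    dropped <- which(drop)
    rekeep <- dropped[sample.int(length(dropped), excess)]
    drop[rekeep] <- FALSE
  }
  !drop
}

#' Evaluate a model on a dataset, optionally with masked modalities
#'
#' Masked modalities are zeroed at the encoded-representation level,
#' identically to training-time modality dropout.
#'
#' @param model A trained `fuseomics_model`.
#' @param dataset A standardized `multiomics_dataset`.
#' @param missing Character vector of modalities to mask (strict subset).
#'
#' @return List with `accuracy`, `per_class` (tibble of class, n, recall),
#'   `confusion` (table, true x predicted) and `missing`.
#' @export
evaluate_model <- function(model, dataset, missing = character()) {
  pred <- predict(model, dataset, missing = missing)
  truth <- as.character(dataset$labels)
  acc <- mean(pred$predicted_class == truth)
  cls <- model$class_names
  confusion <- table(factor(truth, cls), factor(pred$predicted_class, cls),
                     dnn = c("true", "predicted"))
  per_class <- tibble::tibble(
    class = cls,
    n = as.integer(rowSums(confusion)),
    recall = ifelse(rowSums(confusion) > 0,
                    diag(confusion) / rowSums(confusion), NA_real_)
  )
  list(accuracy = acc, per_class = per_class, confusion = confusion,
       missing = missing)
}

#' Accuracy under every missingness pattern
#'
#' Evaluates the model once per subset of missing modalities: the complete
#' case plus every nonempty proper subset (the all-missing pattern is
#' excluded), i.e. `2^M - 1` rows.
#'
#' @param model A trained `fuseomics_model`.
#' @param dataset A standardized `multiomics_dataset`.
#' @param max_modalities Guard: error if the model has more modalities than
#'   this (the grid is exponential in M).
#'
#' @return A tibble of class `missingness_grid` with columns `pattern`
#'   (comma-separated missing modalities, `"<none>"` for the complete case),
#'   `n_missing` and `accuracy`.
#' @export
missingness_grid <- function(model, dataset, max_modalities = 12L) {
  mods <- names(model$encoders)
  M <- length(mods)
  if (M > max_modalities) {
    abort_("2^", M, " - 1 patterns is intractable; evaluate a sampled subset ",
           "of patterns instead")
  }
  rows <- list()
  for (size in 0:(M - 1L)) {
    for (comb in utils::combn(M, size, simplify = FALSE)) {
      miss <- mods[comb]
      acc <- evaluate_model(model, dataset, missing = miss)$accuracy
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pattern = if (length(miss)) paste(miss, collapse = ",") else "<none>",
        n_missing = length(miss), accuracy = acc)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("missingness_grid", class(out))
  out
}

#' Learning-curve sweep over training-set fractions
#'
#' For each fraction, subsamples the training set while preserving class
#' proportions, retrains both phases from scratch, and reports test accuracy.
#'
#' @param train,val,test Standardized `multiomics_dataset`s.
#' @param graph A `modality_graph`.
#' @param fractions Numeric vector of training fractions in (0, 1].
#' @param encoder_configs As in [train_phase1()].
#' @param seed Integer seed (also offsets per-fraction subsampling).
#' @param epochs1,epochs2,batch_size,lr Training hyperparameters.
#'
#' @return Tibble with `fraction`, `n_train`, `accuracy`.
#' @export
subset_size_sweep <- function(train, val, test, graph, fractions,
                              encoder_configs = list(), seed = 1L,
                              epochs1 = 30L, epochs2 = 40L, batch_size = 32L,
                              lr = 1e-3) {
  rows <- list()
  for (i in seq_along(fractions)) {
    fr <- fractions[i]
    sub <- if (fr >= 1) train else subsample_fraction(train, fr, seed = seed + i)
    p1 <- train_phase1(sub, val, encoder_configs, seed = seed,
                       epochs = epochs1, batch_size = batch_size, lr = lr)
    model <- build_model(p1$encoders, graph, class_names = train$class_names,
                         seed = seed)
    p2 <- train_phase2(sub, val, model, seed = seed, epochs = epochs2,
                       batch_size = batch_size, lr = lr)
    acc <- evaluate_model(p2$model, test)$accuracy
    rows[[i]] <- tibble::tibble(fraction = fr, n_train = n_samples(sub),
                                accuracy = acc)
  }
  dplyr::bind_rows(rows)
}

#' Parameter count of a VCDN late-fusion tensor module
#'
#' The view correlation discovery network used by late-fusion architectures
#' requires `C^(2M)` parameters for C classes and M views, which explodes
#' combinatorially (19 classes and 4 views already exceed 16 billion). This
#' analytic utility motivates graph-restricted cross-attention as the
#' integration mechanism instead.
#'
#' @param C Number of classes (>= 1).
#' @param M Number of views/modalities (>= 1).
#' @return `C^(2M)` as a numeric (exact for values below 2^53).
#' @export
vcdn_param_count <- function(C, M) {
  if (C < 1 || M < 1) abort_("C and M must be >= 1")
  as.numeric(C)^(2 * as.numeric(M))
}
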