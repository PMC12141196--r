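test_that("class weights are inverse-frequency with mean one", {
  w <- class_weights(factor(c("A", "A", "A", "B")))
  expect_equal(unname(w), c(4 / 6, 2), tolerance = 1e-12)

  balanced <- class_weights(factor(rep(c("x", "y", "z"), 10)))
  expect_equal(unname(balanced), rep(1, 3))

  # normalization: sum_c w_c * n_c / n = 1
  y <- factor(c(rep("a", 7), rep("b", 2), rep("c", 11)))
  w2 <- class_weights(y)
  expect_equal(sum(w2 * table(y) / length(y)), 1, tolerance = 1e-12)

  expect_error(class_weights(factor("A", levels = c("A", "B"))), "empty class")
})

test_that("with balanced classes the weighted loss equals the unweighted one", {
  logits <- withr::with_seed(1, matrix(rnorm(20 * 4), 20, 4))
  y <- rep(1:4, 5)
  w <- class_weights(factor(y))
  ce_w <- fuseomics:::weighted_ce(logits, y, w)
  ce_u <- fuseomics:::weighted_ce(logits, y, rep(1, 4))
  expect_equal(ce_w$loss, ce_u$loss, tolerance = 1e-12)
  expect_equal(ce_w$dlogits, ce_u$dlogits, tolerance = 1e-12)
})

test_that("dropout masks respect P and the cap", {
  withr::with_seed(1, {
    expect_equal(sample_dropout_mask(5, 0, 4), rep(TRUE, 5))
    # P = 1 with a cap: exactly max_dropped modalities dropped
    for (i in 1:50) {
      m <- sample_dropout_mask(4, 1, 2)
      expect_equal(sum(!m), 2L)
    }
    # cap is never exceeded
    n_drop <- replicate(2e4, sum(!sample_dropout_mask(4, 0.5, 2)))
    expect_true(all(n_drop <= 2))
    # uncapped: per-modality drop frequency within 3 sigma of binomial P
    draws <- replicate(1e4, !sample_dropout_mask(4, 0.5, 3))
    # (cap 3 < 4 can bias the all-dropped case; use P small enough to be rare)
    draws2 <- replicate(1e4, !sample_dropout_mask(4, 0.2, 3))
    freq <- rowMeans(draws2)
    sigma <- sqrt(0.2 * 0.8 / 1e4)
    expect_true(all(abs(freq - 0.2) < 3 * sigma + 0.2 * mean(freq) * 0.01 + 3e-3))
  })
  expect_error(sample_dropout_mask(3, 1.5, 1), "P must")
  expect_error(sample_dropout_mask(3, 0.5, 3), "max_dropped")
})

test_that("VCDN parameter counts grow as C^(2M)", {
  expect_equal(vcdn_param_count(2, 1), 4)
  expect_equal(vcdn_param_count(1, 10), 1)
  expect_equal(vcdn_param_count(3, 2), 81)
  expect_gt(vcdn_param_count(19, 4), 16e9)
  expect_error(vcdn_param_count(0, 2), ">= 1")
})

# a small, strongly separable dataset used by the training contracts below
separable_fixture <- function(seed = 0) {
  spec <- synthetic_spec(
    n_samples = 160,
    class_props = c(a = 0.25, b = 0.25, c = 0.25, d = 0.25),
    modalities = list(list(name = "m1", p = 24L, d = 3.0),
                      list(name = "m2", p = 24L, d = 3.0)),
    planted_edges = list(),
    noise_sd = 1.0, seed = seed
  )
  gen <- generate_multiomics(spec)
  sp <- split_stratified(gen$dataset, c(0.7, 0.15, 0.15), seed = seed + 1)
  std <- standardize_multiomics(sp$train)
  list(train = std$dataset,
       val = standardize_multiomics(sp$val, std$stats)$dataset)
}

enc_cfg2 <- function() list(m1 = list(k = 2L, s = 8L, heads = 2L),
                            m2 = list(k = 2L, s = 8L, heads = 2L))

test_that("phase 1 fits strongly separable data and is deterministic", {
  fx <- separable_fixture(seed = 0)
  p1 <- train_phase1(fx$train, fx$val, enc_cfg2(), seed = 0, epochs = 40, lr = 3e-3)
  # train accuracy of each unimodal encoder+head
  for (nm in c("m1", "m2")) {
    U <- fuseomics:::encode_batch(fx$train$modalities[[nm]]$values,
                                  p1$encoders[[nm]])$U
    lg <- fuseomics:::head_logits_batch(U, p1$heads[[nm]])
    acc <- mean(max.col(lg) == as.integer(fx$train$labels))
    expect_gte(acc, 0.95)
  }
  expect_true(all(c("modality", "epoch", "train_loss", "val_loss")
                  %in% names(p1$history)))

  # zero-epoch run returns an initialized checkpoint with empty metrics
  p0 <- train_phase1(fx$train, fx$val, enc_cfg2(), seed = 0, epochs = 0)
  expect_equal(nrow(p0$history), 0L)
  expect_named(p0$encoders, c("m1", "m2"))

  # determinism: identical seed and config give identical weights
  a <- train_phase1(fx$train, fx$val, enc_cfg2(), seed = 7, epochs = 3)
  b <- train_phase1(fx$train, fx$val, enc_cfg2(), seed = 7, epochs = 3)
  expect_identical(a$encoders$m1$params, b$encoders$m1$params)
  expect_identical(a$heads$m2, b$heads$m2)
})

test_that("phase 2 freezes encoders and improves the validation loss", {
  fx <- separable_fixture(seed = 1)
  p1 <- train_phase1(fx$train, fx$val, enc_cfg2(), seed = 1, epochs = 15)
  graph <- modality_graph(c("m1", "m2"), list(c("m1", "m2")))
  model <- build_model(p1$encoders, graph, class_names = fx$train$class_names,
                       predictor_hidden = 8L, seed = 2)
  before <- p1$encoders$m1$params
  p2 <- train_phase2(fx$train, fx$val, model, seed = 3, epochs = 10)
  expect_true(p2$freeze_check)
  expect_identical(p2$model$encoders$m1$params, before)
  expect_lte(min(p2$history$val_loss), p2$history$val_loss[1])

  # an edgeless graph trains the predictor over unimodal branches only
  g0 <- modality_graph(c("m1", "m2"))
  m0 <- build_model(p1$encoders, g0, class_names = fx$train$class_names,
                    predictor_hidden = 8L, seed = 2)
  p20 <- train_phase2(fx$train, fx$val, m0, seed = 3, epochs = 3)
  expect_true(p20$freeze_check)

  # a graph node without an encoder is rejected up front
  g_bad <- modality_graph(c("m1", "m2", "m3"), list(c("m3", "m1")))
  err <- expect_error(build_model(p1$encoders[c("m1", "m2")], g_bad,
                                  class_names = fx$train$class_names))
  expect_match(conditionMessage(err), "m3")
})

test_that("evaluation handles masked modalities and the missingness grid", {
  fx <- separable_fixture(seed = 2)
  p1 <- train_phase1(fx$train, fx$val, enc_cfg2(), seed = 2, epochs = 15)
  graph <- modality_graph(c("m1", "m2"), list(c("m1", "m2")))
  model <- build_model(p1$encoders, graph, class_names = fx$train$class_names,
                       predictor_hidden = 8L, seed = 3)
  p2 <- train_phase2(fx$train, fx$val, model, seed = 4, epochs = 10)

  ev <- evaluate_model(p2$model, fx$val)
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  expect_equal(sum(ev$confusion), n_samples(fx$val))
  expect_equal(nrow(ev$per_class), 4L)
  expect_error(evaluate_model(p2$model, fx$val, missing = c("m1", "m2")),
               "at least one")

  grid <- missingness_grid(p2$model, fx$val)
  expect_equal(nrow(grid), 2^2 - 1)  # M = 2: <none>, m1, m2
  expect_equal(grid$accuracy[grid$pattern == "<none>"], ev$accuracy)

  # M = 3 gives 7 patterns
  model3 <- tiny_model(p = 6L)
  ds3 <- tiny_dataset(class_counts = c(c1 = 4, c2 = 4, c3 = 4),
                      p = c(a = 6, b = 6, c = 6))
  grid3 <- missingness_grid(model3, ds3)
  expect_equal(nrow(grid3), 7L)
  expect_equal(sort(unique(grid3$n_missing)), 0:2)
  expect_error(missingness_grid(model3, ds3, max_modalities = 2L),
               "intractable")
})

test_that("a perfectly separated model attains accuracy 1 and a diagonal confusion", {
  fx <- separable_fixture(seed = 3)
  p1 <- train_phase1(fx$train, fx$val, enc_cfg2(), seed = 3, epochs = 40, lr = 3e-3)
  graph <- modality_graph(c("m1", "m2"))
  model <- build_model(p1$encoders, graph, class_names = fx$train$class_names,
                       predictor_hidden = 8L, seed = 4)
  p2 <- train_phase2(fx$train, fx$val, model, seed = 5, epochs = 40, lr = 3e-3)
  ev <- evaluate_model(p2$model, fx$train)
  expect_gte(ev$accuracy, 0.95)
  expect_gte(sum(diag(ev$confusion)) / sum(ev$confusion), 0.95)
})
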