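test_that("a single affine layer without bias conserves relevance exactly", {
  W <- withr::with_seed(1, matrix(rnorm(12), 4, 3))
  x <- withr::with_seed(2, rnorm(4))
  z <- as.numeric(x %*% W)
  R_out <- c(0, z[2], 0)  # seed from the second output's score
  res <- lrp_fcn(list(list(W = W, b = numeric(3))), x, R_out, eps = 0,
                 final_relu = FALSE)
  expect_equal(sum(res$R_in), z[2], tolerance = 1e-12)
  expect_equal(res$R_bias, 0)
})

test_that("lrp_fcn matches a hand-coded two-layer epsilon-rule oracle", {
  # fixture weights, printed so the oracle is fully explicit
  W1 <- matrix(c(0.5, -0.3, 0.8,
                 0.2, 0.9, -0.4), 3, 2)
  b1 <- c(0.1, -0.2)
  W2 <- matrix(c(1.0, -0.7,
                 0.3, 0.6), 2, 2)
  b2 <- c(0.05, 0)
  x <- c(1.2, -0.4, 0.7)
  eps <- 1e-6

  # oracle: explicit forward + epsilon rule, elementwise loops
  z1 <- as.numeric(x %*% W1) + b1
  h <- pmax(z1, 0)
  z2 <- as.numeric(h %*% W2) + b2
  cidx <- 1L
  R2 <- c(z2[cidx], 0)
  R1 <- numeric(2)
  for (i in 1:2) {
    for (j in 1:2) {
      R1[i] <- R1[i] + h[i] * W2[i, j] / (z2[j] + eps * sign(z2[j])) * R2[j]
    }
  }
  R0 <- numeric(3)
  for (i in 1:3) {
    for (j in 1:2) {
      R0[i] <- R0[i] + x[i] * W1[i, j] / (z1[j] + eps * sign(z1[j])) * R1[j]
    }
  }

  res <- lrp_fcn(list(list(W = W1, b = b1), list(W = W2, b = b2)), x,
                 R2, eps = eps, final_relu = FALSE)
  expect_equal(res$R_in, R0, tolerance = 1e-6)
  expect_equal(res$out, z2, tolerance = 1e-12)
})

test_that("relevance through the untrained predictor conserves the logit", {
  model <- tiny_model()
  x <- withr::with_seed(4, list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))
  rel <- lrp_relevance(model, x, target_class = 2L)
  # freshly initialized biases are zero, so the FCN-only path conserves the
  # seeded logit up to the epsilon stabilizer
  seed_val <- rel$relevance_logits[2]
  expect_equal(rel$fcn_input_relevance, unname(seed_val), tolerance = 1e-4)
  expect_lte(abs(rel$fcn_input_relevance - seed_val) / abs(seed_val), 0.05)
})

test_that("a dead cross-attention edge receives exactly zero relevance", {
  model <- tiny_model()
  model$edges[["a->c"]]$params$Wo[] <- 0
  x <- withr::with_seed(5, list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))
  rel <- lrp_relevance(model, x, target_class = 1L)
  expect_equal(unname(rel$edge_means[["a->c"]]), 0)
  expect_true(all(rel$edges[["a->c"]] == 0))
  expect_false(all(rel$edges[["b->c"]] == 0))
})

test_that("a single-edge model carries all cross-attention relevance on that edge", {
  model <- tiny_model(k = c(a = 2L, b = 2L, c = 2L),
                      s = c(a = 4L, b = 4L, c = 4L),
                      edges = list(c("a", "c")))
  x <- withr::with_seed(6, list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))
  rel <- lrp_relevance(model, x, target_class = 1L)
  expect_named(rel$edges, "a->c")
  expect_named(rel$edge_means, "a->c")
})

test_that("LRP is deterministic and class-sensitive", {
  model <- tiny_model()
  x <- withr::with_seed(7, list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))
  r1 <- lrp_relevance(model, x, target_class = 1L)
  r2 <- lrp_relevance(model, x, target_class = 1L)
  expect_identical(r1$edge_means, r2$edge_means)
  expect_identical(r1$input, r2$input)
  r3 <- lrp_relevance(model, x, target_class = 3L)
  expect_false(identical(r1$edge_means, r3$edge_means))

  # probability seeding is available as the literal reading
  rp <- lrp_relevance(model, x, target_class = 1L,
                      seed_from_probability = TRUE)
  expect_equal(unname(rp$relevance_logits[1]),
               unname(forward_pass(model, x)$probabilities[1]),
               tolerance = 1e-12)

  expect_error(lrp_relevance(model, x[c("a", "b")], 1L), "missing")
  expect_error(lrp_relevance(model, x, "nope"), "unknown class")
})

test_that("interaction importance aggregates per-sample relevances consistently", {
  model <- tiny_model(p = 6L)
  ds <- tiny_dataset(class_counts = c(c1 = 4, c2 = 4, c3 = 4),
                     p = c(a = 6, b = 6, c = 6))
  rep <- interaction_importance(model, ds)
  expect_s3_class(rep, "relevance_report")
  expect_equal(nrow(rep$samples), 12L * 2L)  # 2 edges per sample

  # class means are re-derivable from the per-sample scores
  recomputed <- dplyr::summarise(
    dplyr::group_by(rep$samples, class, edge),
    m = mean(relevance), .groups = "drop")
  merged <- dplyr::inner_join(recomputed, rep$class_means,
                              by = c("class", "edge"))
  expect_equal(merged$m, merged$mean_relevance, tolerance = 1e-9)
  cohort <- dplyr::summarise(dplyr::group_by(rep$samples, edge),
                             m = mean(relevance), .groups = "drop")
  expect_equal(dplyr::inner_join(cohort, rep$cohort, by = "edge")$m,
               dplyr::inner_join(cohort, rep$cohort, by = "edge")$mean_relevance,
               tolerance = 1e-9)

  # tidiers and plots
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(tidy(rep, level = "cohort")), 2L)
  expect_s3_class(autoplot(rep), "ggplot")

  expect_error(interaction_importance(model, ds, class_filter = "zz"),
               "no samples")
  norm <- interaction_importance(model, ds, normalize = TRUE)
  sums <- tapply(abs(norm$class_means$mean_relevance),
                 norm$class_means$class, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-9)
})
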