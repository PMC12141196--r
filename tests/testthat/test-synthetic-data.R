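skip_if_not_installed("glmnet")

# multinomial ridge oracle used to probe decodability of generated signals
ridge_acc <- function(Xtr, ytr, Xte, yte) {
  fit <- glmnet::glmnet(Xtr, ytr, family = "multinomial", alpha = 0,
                        lambda = 0.05)
  mean(predict(fit, Xte, type = "class") == as.character(yte))
}

split_xy <- function(gen, mod, seed = 1) {
  sp <- split_stratified(gen$dataset, c(0.7, 0.15, 0.15), seed = seed)
  list(Xtr = sp$train$modalities[[mod]]$values, ytr = sp$train$labels,
       Xte = sp$test$modalities[[mod]]$values, yte = sp$test$labels,
       train = sp$train, test = sp$test)
}

test_that("generation honours the spec contract and is reproducible", {
  spec <- default_synthetic_spec(seed = 4)
  gen <- generate_multiomics(spec)
  expect_equal(n_samples(gen$dataset), 600L)
  expect_equal(modality_names(gen$dataset), c("cnv", "mrna", "prot"))
  expect_equal(unname(table(gen$dataset$labels)), rep(150L, 4),
               ignore_attr = TRUE)
  expect_named(gen$truth$planted, c("cnv->mrna", "mrna->prot"))

  gen2 <- generate_multiomics(spec)
  expect_identical(gen$dataset$modalities$mrna$values,
                   gen2$dataset$modalities$mrna$values)
  expect_identical(gen$dataset$labels, gen2$dataset$labels)

  expect_error(synthetic_spec(10, c(a = 0.6, b = 0.6),
                              list(list(name = "m", p = 10, d = 0))),
               "sum to 1")
  expect_error(synthetic_spec(10, c(a = 0.5, b = 0.5),
                              list(list(name = "m", p = 3, d = 0))),
               "p must be >= 4")
})

test_that("without any signal a classifier stays at chance level", {
  accs <- sapply(1:3, function(seed) {
    spec <- synthetic_spec(
      n_samples = 300,
      class_props = c(a = 0.25, b = 0.25, c = 0.25, d = 0.25),
      modalities = list(list(name = "m1", p = 30L, d = 0)),
      planted_edges = list(), noise_sd = 1, seed = seed)
    gen <- generate_multiomics(spec)
    xy <- split_xy(gen, "m1", seed = seed)
    ridge_acc(xy$Xtr, xy$ytr, xy$Xte, xy$yte)
  })
  expect_lt(mean(accs), 0.25 + 0.10)
  expect_gt(mean(accs), 0.25 - 0.10)
})

test_that("unimodal decodability is monotone in the effect size", {
  acc_at_d <- function(d) {
    mean(sapply(1:3, function(seed) {
      spec <- synthetic_spec(
        n_samples = 300,
        class_props = c(a = 0.25, b = 0.25, c = 0.25, d = 0.25),
        modalities = list(list(name = "m1", p = 30L, d = d)),
        planted_edges = list(), noise_sd = 1, seed = seed)
      xy <- split_xy(generate_multiomics(spec), "m1", seed = seed)
      ridge_acc(xy$Xtr, xy$ytr, xy$Xte, xy$yte)
    }))
  }
  a0 <- acc_at_d(0); a1 <- acc_at_d(0.5); a2 <- acc_at_d(2.0)
  expect_gte(a1, a0)
  expect_gte(a2, a1)
  expect_gt(a2, a0 + 0.2)  # strong effects are clearly decodable
})

test_that("the planted interaction is decodable jointly but weak marginally", {
  # the default spec is the regime the capability studies run in
  spec <- default_synthetic_spec(seed = 21)
  gen <- generate_multiomics(spec)
  sp <- split_stratified(gen$dataset, c(0.7, 0.15, 0.15), seed = 22)
  ytr <- sp$train$labels; yte <- sp$test$labels

  # both oracles use cross-validated ridge so neither is favoured by a fixed
  # regularization choice
  cv_acc <- function(Xtr, Xte) {
    fit <- withr::with_seed(1, glmnet::cv.glmnet(
      Xtr, ytr, family = "multinomial", alpha = 0, nfolds = 5))
    mean(predict(fit, Xte, type = "class", s = "lambda.min") ==
           as.character(yte))
  }
  single <- sapply(modality_names(gen$dataset), function(nm) {
    cv_acc(sp$train$modalities[[nm]]$values, sp$test$modalities[[nm]]$values)
  })

  # product-feature oracle: per planted edge, the products of the mean source
  # loading with each planted target feature
  prod_feats <- function(ds) {
    do.call(cbind, lapply(gen$truth$planted, function(tt) {
      src <- rowMeans(ds$modalities[[tt$source]]$values[, tt$source_features])
      src * ds$modalities[[tt$target]]$values[, tt$target_features]
    }))
  }
  prod_acc <- cv_acc(prod_feats(sp$train), prod_feats(sp$test))
  expect_gte(prod_acc, max(single) + 0.15)
})

test_that("export/load round-trips matrices exactly and records the truth", {
  spec <- synthetic_spec(
    n_samples = 30,
    class_props = c(a = 0.5, b = 0.5),
    modalities = list(list(name = "m1", p = 6L, d = 0.5),
                      list(name = "m2", p = 5L, d = 0.5)),
    planted_edges = list(list(source = "m1", target = "m2", gamma = 1,
                              class_signs = c(1, -1))),
    noise_sd = 1, seed = 9)
  gen <- generate_multiomics(spec)
  dir <- withr::local_tempdir()
  graph <- modality_graph(c("m1", "m2"), list(c("m1", "m2")))
  files <- export_multiomics(gen$dataset, dir, truth = gen$truth,
                             graph = graph)
  expect_true(all(file.exists(files)))

  back <- suppressMessages(read_multiomics(
    files[c("m1", "m2")], files[["labels"]]))
  expect_equal(back$modalities$m1$values, gen$dataset$modalities$m1$values)
  expect_equal(back$modalities$m2$values, gen$dataset$modalities$m2$values)
  expect_equal(as.character(back$labels), as.character(gen$dataset$labels))

  truth <- jsonlite::fromJSON(files[["ground_truth"]])
  expect_named(truth$planted, "m1->m2")
  g2 <- read_modality_graph(files[["graph"]])
  expect_equal(g2$edges, graph$edges)

  # unwritable destination: error up front, no partial files
  bad <- file.path(dir, "no", "such", "parent", "out")
  expect_error(export_multiomics(gen$dataset, bad), "not writable")
  expect_false(dir.exists(dirname(bad)))
})
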