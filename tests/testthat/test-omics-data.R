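test_that("reading aligned matrices keeps the shared samples in label order", {
  dir <- withr::local_tempdir()
  ids <- c("a", "b", "c")
  m1 <- write_matrix_tsv(matrix(1:6, 3, 2,
                                dimnames = list(NULL, c("f1", "f2"))),
                         ids, file.path(dir, "m1.tsv"))
  m2 <- write_matrix_tsv(matrix(7:12, 3, 2,
                                dimnames = list(NULL, c("g1", "g2"))),
                         c("b", "c", "d"), file.path(dir, "m2.tsv"))
  lab <- write_labels_csv(c("b", "c"), c("x", "y"), file.path(dir, "lab.csv"))

  msgs <- capture_messages(
    ds <- read_multiomics(c(m1 = m1, m2 = m2), lab)
  )
  expect_equal(n_samples(ds), 2L)
  expect_equal(sample_ids(ds), c("b", "c"))
  expect_equal(as.character(ds$labels), c("x", "y"))
  # each matrix file dropped exactly one sample (a and d respectively)
  expect_match(msgs[grepl("'m1'", msgs)], "dropped 1")
  expect_match(msgs[grepl("'m2'", msgs)], "dropped 1")
  # values follow the kept rows of each file
  expect_equal(unname(ds$modalities$m1$values["b", ]), c(2, 5))
})

test_that("identity case: all files share all samples", {
  dir <- withr::local_tempdir()
  ids <- sprintf("s%02d", 1:10)
  paths <- sapply(1:3, function(i) {
    write_matrix_tsv(matrix(rnorm(20), 10, 2,
                            dimnames = list(NULL, c("f1", "f2"))),
                     ids, file.path(dir, paste0("mod", i, ".tsv")))
  })
  names(paths) <- paste0("mod", 1:3)
  lab <- write_labels_csv(ids, rep(c("x", "y"), 5), file.path(dir, "lab.csv"))
  ds <- suppressMessages(read_multiomics(paths, lab))
  expect_equal(length(ds$modalities), 3L)
  expect_equal(n_samples(ds), 10L)
})

test_that("reader errors: empty intersection, NaN cells, duplicates, unknown class", {
  dir <- withr::local_tempdir()
  m1 <- write_matrix_tsv(matrix(1:4, 2, 2, dimnames = list(NULL, c("f1", "f2"))),
                         c("a", "b"), file.path(dir, "m1.tsv"))
  lab_cd <- write_labels_csv(c("c", "d"), c("x", "y"), file.path(dir, "l1.csv"))
  expect_error(suppressMessages(read_multiomics(c(m1 = m1), lab_cd)),
               "no sample id is shared")

  bad <- matrix(c(1, NaN, 3, 4), 2, 2, dimnames = list(NULL, c("f1", "f2")))
  m2 <- write_matrix_tsv(bad, c("a", "b"), file.path(dir, "m2.tsv"))
  lab_ab <- write_labels_csv(c("a", "b"), c("x", "y"), file.path(dir, "l2.csv"))
  err <- expect_error(read_multiomics(c(m2 = m2), lab_ab))
  expect_match(conditionMessage(err), "m2.tsv")
  expect_match(conditionMessage(err), "f1")  # names the offending column

  m3 <- write_matrix_tsv(matrix(1:4, 2, 2, dimnames = list(NULL, c("f1", "f2"))),
                         c("a", "a"), file.path(dir, "m3.tsv"))
  expect_error(read_multiomics(c(m3 = m3), lab_ab), "duplicate sample id")

  expect_error(
    suppressMessages(read_multiomics(c(m1 = m1), lab_ab,
                                     class_names = c("x", "z"))),
    "not in class_names")
})

test_that("standardization fits, applies and treats constant columns safely", {
  vals <- cbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5))
  ds <- multiomics_dataset(list(m = omics_matrix(vals, "m")), c("a", "a", "b"))
  expect_warning(out <- standardize_multiomics(ds), "zero-variance")
  std <- out$dataset$modalities$m$values
  expect_equal(mean(std[, "f1"]), 0, tolerance = 1e-12)
  expect_equal(sd(std[, "f1"]), 1, tolerance = 1e-12)
  expect_equal(unname(std[, "f2"]), c(0, 0, 0))

  # applying train-fitted stats: (4 - 2) / 1 = 2
  stats <- list(m = list(mean = c(f1 = 2, f2 = 5), sd = c(f1 = 1, f2 = 1),
                         zero_var = c(f1 = FALSE, f2 = TRUE)))
  test_ds <- multiomics_dataset(
    list(m = omics_matrix(cbind(f1 = 4, f2 = 9), "m", sample_ids = "s1")), "a")
  applied <- standardize_multiomics(test_ds, stats = stats)
  expect_equal(unname(applied$dataset$modalities$m$values[1, "f1"]), 2)

  # idempotence: re-applying the fitted stats reproduces the fit-transform
  again <- standardize_multiomics(ds, stats = out$stats)
  expect_equal(again$dataset$modalities$m$values, std)
})

test_that("stratified split allocates largest-remainder exact counts", {
  ds <- tiny_dataset(class_counts = c(c1 = 500, c2 = 500, c3 = 500, c4 = 500),
                     p = c(m1 = 3))
  sp <- split_stratified(ds, c(0.70, 0.15, 0.15), seed = 7)
  expect_equal(n_samples(sp$train), 1400L)
  expect_equal(n_samples(sp$val), 300L)
  expect_equal(n_samples(sp$test), 300L)
  expect_equal(unname(table(sp$train$labels)), rep(350L, 4), ignore_attr = TRUE)
  expect_equal(unname(table(sp$val$labels)), rep(75L, 4), ignore_attr = TRUE)

  all_train <- split_stratified(ds, c(1, 0, 0), seed = 1)
  expect_equal(n_samples(all_train$train), 2000L)
  expect_equal(n_samples(all_train$val), 0L)

  # determinism
  sp2 <- split_stratified(ds, c(0.70, 0.15, 0.15), seed = 7)
  expect_identical(sample_ids(sp$train), sample_ids(sp2$train))
  expect_identical(sample_ids(sp$test), sample_ids(sp2$test))
})

test_that("split partitions are exhaustive and disjoint for random class mixes", {
  for (seed in 1:5) {
    counts <- withr::with_seed(seed, sample(3:40, sample(2:5, 1)))
    names(counts) <- paste0("k", seq_along(counts))
    ds <- tiny_dataset(class_counts = counts, p = c(m1 = 2), seed = seed)
    sp <- split_stratified(ds, c(0.6, 0.2, 0.2), seed = seed)
    got <- c(sample_ids(sp$train), sample_ids(sp$val), sample_ids(sp$test))
    expect_setequal(got, sample_ids(ds))
    expect_equal(length(got), length(unique(got)))
  }
})

test_that("split refuses classes with fewer than 3 samples", {
  ds <- tiny_dataset(class_counts = c(big = 10, tiny = 2), p = c(m1 = 2))
  expect_error(split_stratified(ds, seed = 1), "tiny")
})

test_that("subsampling preserves class proportions with a floor of one", {
  ds <- tiny_dataset(class_counts = c(a = 100, b = 100, c = 100, d = 100),
                     p = c(m1 = 2))
  sub <- subsample_fraction(ds, 0.10, seed = 3)
  expect_equal(n_samples(sub), 40L)
  expect_equal(unname(table(sub$labels)), rep(10L, 4), ignore_attr = TRUE)

  # identity at fraction 1 (same sample set)
  full <- subsample_fraction(ds, 1.0, seed = 3)
  expect_setequal(sample_ids(full), sample_ids(ds))

  # max(1, .) floor
  ds3 <- tiny_dataset(class_counts = c(a = 3, b = 50), p = c(m1 = 2))
  sub3 <- subsample_fraction(ds3, 0.01, seed = 1)
  expect_equal(sum(sub3$labels == "a"), 1L)

  expect_error(subsample_fraction(ds, 0), "fraction")
  expect_error(subsample_fraction(ds, 1.2), "fraction")

  # proportions deviate by at most one sample per class from exact scaling
  for (seed in 1:3) {
    counts <- c(a = 37, b = 11, c = 52)
    dsx <- tiny_dataset(class_counts = counts, p = c(m1 = 2), seed = seed)
    fr <- 0.3
    subx <- subsample_fraction(dsx, fr, seed = seed)
    got <- table(subx$labels)
    expect_true(all(abs(as.numeric(got) - counts * fr) <= 1))
  }
})

test_that("dataset constructor enforces alignment and labelling", {
  m1 <- omics_matrix(matrix(1:4, 2, 2), "m1", sample_ids = c("a", "b"))
  m2 <- omics_matrix(matrix(1:4, 2, 2), "m2", sample_ids = c("b", "a"))
  expect_error(multiomics_dataset(list(m1 = m1, m2 = m2), c("x", "y")),
               "sample ids differ")
  expect_error(multiomics_dataset(list(m1 = m1), c("x", "y", "z")),
               "length")
  expect_error(multiomics_dataset(list(m1 = m1), c("x", "q"),
                                  class_names = c("x", "y")),
               "not in class_names")
})
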