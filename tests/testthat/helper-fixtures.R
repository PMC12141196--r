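# Fixture builders shared across test files. Everything is generated in code;
# no data files are stored.

# A small aligned dataset with given per-class counts and feature counts.
tiny_dataset <- function(class_counts = c(a = 6, b = 6), p = c(m1 = 5, m2 = 4),
                         seed = 1) {
  n <- sum(class_counts)
  labels <- rep(names(class_counts), class_counts)
  ids <- sprintf("s%03d", seq_len(n))
  mods <- lapply(names(p), function(nm) {
    vals <- withr::with_seed(seed + match(nm, names(p)), {
      matrix(rnorm(n * p[[nm]]), n, p[[nm]])
    })
    rownames(vals) <- ids
    colnames(vals) <- paste0(nm, "_f", seq_len(p[[nm]]))
    omics_matrix(vals, nm)
  })
  names(mods) <- names(p)
  multiomics_dataset(mods, labels)
}

# Write a samples x features matrix as the TSV dialect read_multiomics expects.
write_matrix_tsv <- function(values, ids, path) {
  df <- data.frame(sample_id = ids, values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_labels_csv <- function(ids, classes, path) {
  write.table(data.frame(sample_id = ids, class = classes), path, sep = ",",
              quote = FALSE, row.names = FALSE)
  path
}

# Random encoded-modality array for attention-level tests.
rand_U <- function(n, k, s, seed = 1) {
  withr::with_seed(seed, array(rnorm(n * k * s), c(n, k, s)))
}

# Random single-sample encoded modality (k x s matrix).
rand_encoded <- function(k, s, name = "m", seed = 1) {
  structure(list(modality_name = name,
                 U = withr::with_seed(seed, matrix(rnorm(k * s), k, s))),
            class = "encoded_modality")
}

# A small untrained model over a 3-node graph (a->c, b->c), a and b unimodal.
tiny_model <- function(k = c(a = 2L, b = 3L, c = 2L),
                       s = c(a = 4L, b = 8L, c = 8L),
                       p = 10L, C = 3L, seed = 5, edges = list(c("a", "c"),
                                                               c("b", "c"))) {
  graph <- modality_graph(names(k), edges)
  encs <- lapply(names(k), function(nm) {
    part <- make_partition(p, k[[nm]], seed = seed + 10, modality_name = nm)
    encoder_init(part, s = s[[nm]], heads = 2L, seed = seed + 20)
  })
  names(encs) <- names(k)
  build_model(encs, graph, class_names = paste0("c", seq_len(C)),
              predictor_hidden = 8L, seed = seed)
}
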